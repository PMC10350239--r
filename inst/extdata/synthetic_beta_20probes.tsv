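probe_id	S01_a	S02_a	S03_a	S04_a	S05_a	S06_a	S01_b	S02_b	S03_b	S04_b	S05_b	S06_b
cgTEST001	0.588988	0.647012	0.999999	0.822886	0.762958	0.910485	0.997971	0.754058	0.863427	0.82189	0.990123	0.932853
cgTEST002	0.448556	0.454883	0.519084	0.325773	0.282938	0.413057	0.352383	0.405691	0.548921	0.359013	0.190655	0.416438
cgTEST003	0.430434	0.320218	0.332513	0.469418	0.39899	0.186074	0.313233	0.272827	0.341891	0.501027	0.330034	0.303137
cgTEST004	0.753881	0.4248	0.819531	0.565539	0.669844	0.077364	0.77929	0.534861	0.798053	0.449429	0.644116	0.184732
cgTEST005	0.464097	0.338664	0.932086	0.527702	0.782666	0.673605	0.701068	0.427379	0.719769	0.793381	0.812571	0.617773
cgTEST006	0.619899	0.919105	0.98705	0.999999	0.875744	0.695352	0.660761	0.978025	0.672363	0.999999	0.875403	0.896243
cgTEST007	0.806151	0.707373	0.670758	0.762203	0.909978	0.219333	0.634679	0.774614	0.891539	0.701784	0.999999	0.306675
cgTEST008	0.04097	0.27229	0.129736	0.015454	0.118789	0.19857	0.060138	0.061012	0.237052	1e-06	0.038534	0.24289
cgTEST009	0.659253	0.84802	0.846818	0.999999	0.394644	0.571865	0.870649	0.999999	0.687041	0.762826	0.580706	0.556309
cgTEST010	0.993801	0.823569	0.338086	0.802745	0.906621	0.643073	0.973383	0.71612	0.422213	0.80213	0.79495	0.628399
cgTEST011	0.484372	0.164058	0.003239	0.003297	0.279846	0.500825	0.269909	0.34848	1e-06	0.119341	0.343971	0.125153
cgTEST012	0.442237	0.445852	0.605397	0.740129	0.57116	0.617875	0.4068	0.42614	0.701415	0.847473	0.104109	0.847591
cgTEST013	1e-06	0.463897	0.429494	1e-06	0.378762	0.754102	0.023774	0.525841	0.468935	1e-06	0.287214	0.678531
cgTEST014	0.841423	0.354017	0.483418	0.745166	0.999999	0.894764	0.965995	0.518249	0.72218	0.700713	0.797918	0.999999
cgTEST015	0.752541	0.933747	0.584521	0.971768	0.731357	0.970887	0.823758	0.64374	0.765336	0.565052	0.765184	0.859312
cgTEST016	0.797446	0.874617	0.995146	0.866258	0.999999	0.873245	0.796227	0.841781	0.973423	0.966899	0.682727	0.905946
cgTEST017	0.436309	0.337362	0.305997	0.251464	0.451915	0.457255	0.471969	0.268793	0.266465	0.195876	0.47319	0.45146
cgTEST018	0.722932	0.850331	0.738356	0.623239	0.755773	0.636344	0.6646	0.84356	0.791852	0.813748	0.831851	0.71861
cgTEST019	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5
cgTEST020	0.249544	0.387574	0.001649	0.146964	0.04617	1e-06	0.285399	0.184367	NA	0.133694	0.000176	0.142371
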