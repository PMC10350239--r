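sample_id,subject_id,replicate,plate
S01_a,S01,1,P1
S02_a,S02,1,P1
S03_a,S03,1,P1
S04_a,S04,1,P1
S05_a,S05,1,P1
S06_a,S06,1,P1
S01_b,S01,2,P2
S02_b,S02,2,P2
S03_b,S03,2,P2
S04_b,S04,2,P2
S05_b,S05,2,P2
S06_b,S06,2,P2
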