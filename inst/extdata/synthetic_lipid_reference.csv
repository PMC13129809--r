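name,monoisotopic_mz,class
synthetic PI 38:4,886.5572,PI
synthetic PS 40:6,834.5261,PS
synthetic PE 38:4,767.5465,PE
synthetic PG 34:1,748.5254,PG
synthetic ST 24:1;O4,888.6238,ST
synthetic PC 32:0,733.5622,PC
synthetic SM 36:1;O2,728.5832,SM
synthetic GM1 36:1;O2,1545.8810,GM
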