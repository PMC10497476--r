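label,name,K1,k2,k3,Vb,is_blood
1,blood,0,0,0,1,1
2,lesion,0.094,0.3,0.1,0.05,0
3,gray_matter,0.146,0.3,0.1,0.04,0
4,white_matter,0.0696,0.25,0.05,0.03,0
5,lung,0.0072,0.35,0.05,0.15,0
6,liver,0.37,0.99,0.01,0.10,0
7,spleen,0.18,0.78,0.02,0.12,0
8,bone_marrow,0.0392,0.3,0.1,0.04,0
9,kidney,0.099,0.85,0.05,0.15,0
10,muscle,0.016,0.27,0.03,0.02,0
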