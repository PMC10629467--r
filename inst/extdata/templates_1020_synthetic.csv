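class,Fp1,Fp2,F7,F3,Fz,F4,F8,T3,C3,Cz,C4,T4,T5,P3,Pz,P4,T6,O1,O2
A,-0.178641,-0.350603,0.061495,-0.013913,-0.153041,-0.264344,-0.388725,0.278257,0.139128,0,-0.139128,-0.278257,0.388725,0.264344,0.153041,0.013913,-0.061495,0.350603,0.178641
B,-0.350603,-0.178641,-0.388725,-0.264344,-0.153041,-0.013913,0.061495,-0.278257,-0.139128,0,0.139128,0.278257,-0.061495,0.013913,0.153041,0.264344,0.388725,0.178641,0.350603
C,-0.195008,-0.195008,-0.19265,-0.178228,-0.174007,-0.178228,-0.19265,-0.173021,-0.045851,0.084563,-0.045851,-0.173021,-0.040433,0.263724,0.590959,0.263724,-0.040433,0.310707,0.310707
D,-0.046961,-0.046961,-0.117502,0.215637,0.498923,0.215637,-0.117502,-0.176316,0.160219,0.557774,0.160219,-0.176316,-0.201748,-0.116394,-0.071474,-0.116394,-0.201748,-0.209545,-0.209545
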