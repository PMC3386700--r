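vesicle_id,composition,mole_ratio,ph
V1,DMPC/PDA,2:3,8
V2,DOPC/PDA,2:3,7.4
V3,DMPC/Chl/PDA,1:1:3,8
V4,DMPC/Chl/PDA,1.5:0.5:3,8
V5,DMPE/PS/PDA,1:1:3,8
V6,DMPE/DMPG/PDA,1:1:3,8
V7,DMPE/PI/PDA,1:1:3,8
V8,SM/Chl/PDA,1.5:0.5:3,8.2
V9,DOPE/PDA,2:3,7.6
V10,DOPC/CL/PDA,1:1:3,7.8
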