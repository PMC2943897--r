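category	ligand	receptor	ligand_probe	receptor_probe	printed_block
Angiogenesis	ANGPTL1	TEK	ANGPTL1_p1	TEK_p1	down
Angiogenesis	VEGF	FLT1	VEGF_p1	FLT1_p1	down
Angiogenesis	VEGF	KDR	VEGF_p1	KDR_p1	down
Angiogenesis	VEGF	NRP1	VEGF_p1	NRP1_p1	down
Cytokines	IFNA4	IFNAR2	IFNA4_p1	IFNAR2_p1	up
Cytokines	IFNA7	IFNAR2	IFNA7_p1	IFNAR2_p1	up
Cytokines	TNFSF10	TNFRSF11B	TNFSF10_p1	TNFRSF11B_p1	down
Chemokines	CCL13	CCR3	CCL13_p1	CCR3_p1	up
Chemokines	CCL13	CCR1	CCL13_p1	CCR1_p1	up
Chemokines	CXCL12	CXCR4	CXCL12_p1	CXCR4_p1	down
Growth factors	AREG	EGFR	AREG_p1	EGFR_p1	up
Growth factors	BMP7	ACVR1	BMP7_p1	ACVR1_p1	up
Growth factors	BTC	EGFR	BTC_p1	EGFR_p1	up
Growth factors	BTC	ERBB3	BTC_p1	ERBB3_p1	up
Growth factors	DTR	EGFR	DTR_p1	EGFR_p1	up
Growth factors	INHBA	ACVR1	INHBA_p1	ACVR1_p1	up
Growth factors	INHBB	ACVR1	INHBB_p1	ACVR1_p1	up
Growth factors	JAG2	NOTCH2	JAG2_p1	NOTCH2_p1	up
Growth factors	JAG2	NOTCH3	JAG2_p1	NOTCH3_p1	up
Growth factors	TGFA	EGFR	TGFA_p1	EGFR_p1	up
Growth factors	TGFB1	TGFBR1	TGFB1_p1	TGFBR1_p1	up
Growth factors	TNC	ANXA2	TNC_p1	ANXA2_p1	up
Growth factors	BMP2	BMPR1A	BMP2_p1	BMPR1A_p1	down
Growth factors	BMP7	BMPR1A	BMP7_p2	BMPR1A_p1	down
Growth factors	FGF7	FGFR2	FGF7_p1	FGFR2_p1	down
Growth factors	FGF11	FGFR2	FGF11_p1	FGFR2_p1	down
Growth factors	FGF13	FGFR2	FGF13_p1	FGFR2_p1	down
Growth factors	PTN	PTPRB	PTN_p1	PTPRB_p1	down
Growth factors	TGFB1	TGFBR2	TGFB1_p2	TGFBR2_p1	down
Growth factors	TGFB1	TGFBR3	TGFB1_p2	TGFBR3_p1	down
Motility/adhesion	EFNA3	EPHA4	EFNA3_p1	EPHA4_p1	up
Motility/adhesion	EFNA4	EPHA4	EFNA4_p1	EPHA4_p1	up
Motility/adhesion	LGALS1	SPN	LGALS1_p1	SPN_p1	up
Motility/adhesion	PLAU	PLAUR	PLAU_p1	PLAUR_p1	up
Motility/adhesion	SEMA3F	NRP2	SEMA3F_p1	NRP2_p1	up
Motility/adhesion	SEMA3B	NRP2	SEMA3B_p1	NRP2_p1	up
Motility/adhesion	SPP1	ITGAV	SPP1_p1	ITGAV_p1	up
Motility/adhesion	SPP1	CD44	SPP1_p1	CD44_p1	up
Motility/adhesion	SPP1	ITGA9	SPP1_p1	ITGA9_p1	up
Motility/adhesion	SPP1	ITGB1	SPP1_p1	ITGB1_p1	up
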