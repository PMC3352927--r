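# Angiogenesis validation: 18 known angiogenesis inhibitors and 10 negative
# compounds (no anti-angiogenic action in prior HUVEC/xenopus screens).
# IC50 columns (total vessels / complete vessels, uM) are given only where a
# clear dose-dependent effect allowed a fit; otherwise the minimum effective
# concentration is given. The "?" entry for Paclitaxel (yolk injection,
# effective dose not established) is transcribed verbatim.
compound,human_effect,observed_effect,verdict,ic50_tv_um,ic50_cv_um,effective_um
KRN633,Angiogenesis inhibitor,Inhibited,TP,0.035,0.026,
ZD6474 (Vandetanib),Angiogenesis inhibitor,Inhibited,TP,,,100
Sunitinib malate,Angiogenesis inhibitor,Inhibited,TP,2.6,1.7,
Sorafenib Tosylate,Angiogenesis inhibitor,Inhibited,TP,0.78,0.53,
PD173074,Angiogenesis inhibitor,Inhibited,TP,,,100
PD166866,Angiogenesis inhibitor,Inhibited,TP,43.9,16,
AG-1296,Angiogenesis inhibitor,Inhibited,TP,,,20
PDGFR tyr kin inhibitor V,Angiogenesis inhibitor,Inhibited,TP,0.19,0.14,
Tie2 Kinase inhibitor,Angiogenesis inhibitor,Not inhibited,FN,,,
Bosutinib,Angiogenesis inhibitor,Inhibited,TP,,,50
AG1478,Angiogenesis inhibitor,Inhibited,TP,22.8,13,
Indirubin-3'-oxime,Angiogenesis inhibitor,Inhibited,TP,18.3,4.2,
Fumagillin,Angiogenesis inhibitor,Not inhibited,FN,,,
NS-398,Angiogenesis inhibitor,Inhibited,TP,,,30
HIF-1 Inhibitor,Angiogenesis inhibitor,Not inhibited,FN,,,
NVP-BEZ235,Angiogenesis inhibitor,Inhibited,TP,,,10
2-Methoxyestradiol,Angiogenesis inhibitor,Inhibited,TP,30.6,10.2,
Paclitaxel,Angiogenesis inhibitor,Inhibited,TP,,,?
Tyrphostin AG490,No effect,Not inhibited,TN,,,
Bestatin,No effect,Not inhibited,TN,,,
Acetamide,No effect,Not inhibited,TN,,,
E64,No effect,Not inhibited,TN,,,
O6-benzylguanine,No effect,Not inhibited,TN,,,
Cyclosporine A,No effect,Not inhibited,TN,,,
4-Methylpyrazole hydrochloride,No effect,Not inhibited,TN,,,
N-Acetyl-L-cysteine,No effect,Not inhibited,TN,,,
Amiodarone hydrochloride,No effect,Not inhibited,TN,,,
cis-Diammineplatinum(II) dichloride,No effect,Not inhibited,TN,,,
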