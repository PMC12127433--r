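receptor,ligand,conc_low,conc_high,conc_unit,molar_mass_g_per_mol
AhR,benzo(a)pyrene,NA,NA,NA,252.31
GR,cortisol,65,92,ng/ml,362.46
LXR,24S-hydroxycholesterol,35,62,ng/ml,402.65
LXR,27-hydroxycholesterol,21,39,ng/ml,402.65
PPARa,arachidonic acid,86.6,145.4,ug/ml,304.47
PPARbd,linoleic acid,84,154,ug/ml,280.45
PPARg,docosahexaenoic acid,41.7,75.9,ug/ml,328.49
PR,progesterone,176.4,2818,ng/ml,314.46
PGE2R,prostaglandin E2,9.5,9.5,ng/ml,352.47
RAR,all-trans retinoic acid,30,150.2,ng/ml,300.44
RXR,docosahexaenoic acid,41.7,75.9,ug/ml,328.49
THR,triiodothyronine,0.543,0.606,ng/ml,650.97
VDR,25-hydroxyvitamin D,16.6,16.6,ng/ml,400.64
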