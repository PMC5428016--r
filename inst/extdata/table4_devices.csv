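reference,trapping_mechanism,cell_lines,diameter_um,vm_over_vt,t_exp_h,sample_kind
Frimat 2011,resistive,SW580;HT29;MCF-7,17.9,112,,single cell
Kukhtevich 2015,resistive,K562,20,127,,single cell
Occhetta 2015,resistive,HeLa,16,729,,single cell
Das 2013,resistive,TOV112D,250,138,24,spheroid
Ota 2011,inertial,HepG2,450,168,,spheroid
Astolfi 2016,sedimentation,22Rv1;PC3;TOV112D;OV90,380,208,48,micro-dissected tissue
Anada 2012,sedimentation,HepG2,600,52,24,spheroid
Patra 2016,sedimentation,TOV3041G;TOV112D;OV90;OV866(2),130,53,12,spheroid
Patra 2013,sedimentation,HepG2,225,92,24,spheroid
Frey 2014,open microfluidics,HCT-116 eGFP,400,470,,spheroid
Marimuthu 2018,open microfluidics,OV90,500,378,24,spheroid
Grimes 2014,open microfluidics,DLD1,585,79,24,spheroid
Torisawa 2007,open microfluidics,MCF-7;HepG2,260,165,48,spheroid
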