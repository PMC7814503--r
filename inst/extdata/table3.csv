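accession,ws,dtf,dtf_censored,ppd_h2,ppd_h1,vrn_h1,zcct_ha,zcct_hb,zcct_hc,vrn_h2_status
GRETE,55,60,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,absent,absent,absent,complete_deletion
MW09S4076-002,65,58,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,absent,absent,present,partial_deletion
06OR-20,58,73,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,absent,absent,absent,complete_deletion
07OR-55,56,82,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,absent,absent,absent,complete_deletion
OBADV11-2,58,89,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,absent,absent,absent,complete_deletion
MW09S4086-001,59,69,FALSE,intact_HvFT3,dominant_PPD-H1,intact_intron1,absent,absent,present,partial_deletion
NB09433,63,135,FALSE,intact_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
NB10403,56,137,FALSE,intact_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
NB10417,57,128,FALSE,intact_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
CETIN,62,118,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,NA,NA,NA,partial_deletion
DIADEM,64,141,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,present,present,absent,partial_deletion
JET,55,131,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,NA,NA,NA,partial_deletion
NB09432,65,133,FALSE,intact_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
LENINAKANSKIJ,60,143,FALSE,novel_deletion,recessive_ppd-H1,intact_intron1,present,present,present,intact
NB09441,57,126,FALSE,intact_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
NB10419,62,114,FALSE,intact_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
P-721,55,103,FALSE,intact_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
2011-F5-141-5,62,127,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
2011-F5-36-3,69,154,TRUE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
NB07411,56,139,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
NB10444,59,123,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
NB99875,65,112,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,present,present,present,intact
MO_B475,72,116,FALSE,truncated_HvFT3,dominant_PPD-H1,intact_intron1,NA,NA,NA,partial_deletion
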