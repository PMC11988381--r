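compound,cas_id,CAR,AR,PXR,PPARa,PPARg,PPARd,RORgt
"4,4'-isopropylidenediphenol",80-05-7,-8.6,-8.2,-8.4,-6.9,-7,-7.5,-7
"4,4'-sulphonyldiphenol",80-09-1,-7.8,-7.6,-7.6,-6.7,-7,-7.6,-7
"4,4'-methylenediphenol",620-92-8,-7.5,-7.4,-7.5,-7.2,-7.7,-7,-7.7
"4,4'-(1-methylpropylidene)bisphenol",77-40-7,-8.5,-7.9,-8.4,-6.9,-7,-7.7,-7
"4,4'-[2,2,2-trifluoro-1-(trifluoromethyl)ethylidene]diphenol",1478-61-1,-8.7,-7.8,-9.7,-7.1,-7.3,-7.6,-7.3
"4,4'-(1,3-phenylene-bis(1-methylethylidene))bisphenol",13595-25-0,-11.2,-8.3,-9.4,-7.1,-9.9,#N/A,#N/A
"4,4'-(1-Phenylethylidene)bisphenol",1571-75-1,-9.2,-7.2,-7.6,-6.4,-7.7,-8.8,-7.7
"9,9-Bis(4-hydroxyphenyl)fluorene",3236-71-3,-6.7,-6,-8.4,-7.5,-8,-7,-8
"Biphenyl-4,4'-diol",92-88-6,-7.5,-7.5,-7.2,-6.8,-7.3,-6.9,-7.3
"4,4'-isopropylidenedi-o-cresol",79-97-0,-8.9,#N/A,-9,-7,-8,-8,-8
"4,4'-(dichlorovinylidene)diphenol",14868-03-02,-7.9,-8.1,-7.7,-5.9,-7.3,-7.7,-7.3
"4,4'-(1,4-Phenylenediisopropylidene)bisphenol",2167-51-3,-7.2,-6.5,-9.5,-8.6,-8.7,-8.9,-8.7
"4,4'-cyclohexylidenebisphenol",843-55-0,-8.8,-7.6,-8.3,-6.7,-6.5,-8.2,-6.5
"2,2-bis(2-hydroxy-5-biphenylyl)propane",24038-68-4,-11.5,-6.8,-9.6,-10.3,-9.8,-11.1,-9.8
"4,4'-ihydroxytetraphenylmethane",1844-01-05,-5.9,-5.6,-8.3,-6.5,-7.7,-8.7,-7.7
"4,4'-(1,3-phenylene-bis(1-methylethylidene))bis-phenol",13595-25-0,-11.2,-8.3,-9.4,-7.1,-9.9,#N/A,#N/A
"9,9-Bis(4-hydroxyphenyl)fluorene",3236-71-3,-6.7,-6,-8.4,-7.5,-8,-7,-8
"4,4'-cyclohexylidenebisphenol",843-55-0,-8.8,-7.6,-8.3,-6.7,-6.5,-8.2,-6.5
"Biphenyl-4,4'-diol",92-88-6,-7.5,-7.5,-7.2,-6.8,-7.3,-6.9,-7.3
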