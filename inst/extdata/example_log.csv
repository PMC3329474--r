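date,detector,transgressor,type,hazard
2007-01-04,DEU,IRN,alert,aflatoxin in pistachio kernels
2007-01-19,ITA,CHN,border_rejection,cadmium in frozen squid
2007-02-02,ESP,BRA,information,salmonella in poultry meat
2007-02-20,DEU,IRN,border_rejection,ochratoxin in dried figs
2007-03-08,NLD,IND,alert,nitrofuran in shrimp
2007-03-27,FRA,TUR,alert,aflatoxin in dried figs
2007-04-11,GBR,CHN,information,lead in rice noodles
2007-05-01,ITA,IRN,alert,aflatoxin in pistachio kernels
2007-05-23,DEU,DEU,information,dioxins in animal feed
2007-06-14,ESP,CHN,border_rejection,colour sudan 1 in paprika powder
2007-07-03,DNK,BRA,alert,listeria monocytogenes in smoked salmon
2007-08-21,ITA,TUR,information,incorrect labelling of allergens
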