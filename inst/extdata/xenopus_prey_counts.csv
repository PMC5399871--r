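site,group,taxon,habitat_class,N,V,Freq
CoGH,environment,Anisoptera,nekton,38,2656.01,NA
CoGH,environment,Brachycera,terrestrial,0,0,NA
CoGH,environment,Coleoptera,nekton,9,8405.49,NA
CoGH,environment,Ephemeroptera,benthos,8,59.36,NA
CoGH,environment,Heteroptera,nekton,61,660.07,NA
CoGH,environment,Hymenoptera,terrestrial,0,0,NA
CoGH,environment,Nematocera,terrestrial,49,68.42,NA
CoGH,environment,Neuroptera,terrestrial,0,0,NA
CoGH,environment,Psocoptera,terrestrial,1,0.78,NA
CoGH,environment,Trichoptera,benthos,29,106.48,NA
CoGH,environment,Zygoptera,nekton,2368,55275.07,NA
CoGH,environment,Zygentoma,terrestrial,1,1.41,NA
CoGH,environment,Amphipoda,nekton,7,14.26,NA
CoGH,environment,Daphnia,zooplankton,98,139.67,NA
CoGH,environment,Ostracoda,benthos,173,26.24,NA
CoGH,environment,Aranae,terrestrial,1,1.28,NA
CoGH,environment,Acari,nekton,13,0.42,NA
CoGH,environment,Scorpiones,terrestrial,0,0,NA
CoGH,environment,Anura,nekton,17,3092.02,NA
CoGH,X_laevis,Anisoptera,nekton,27,1394.94,14
CoGH,X_laevis,Brachycera,terrestrial,3,56.93,1
CoGH,X_laevis,Coleoptera,nekton,20,199.16,11
CoGH,X_laevis,Ephemeroptera,benthos,0,0,0
CoGH,X_laevis,Heteroptera,nekton,15,152.81,8
CoGH,X_laevis,Hymenoptera,terrestrial,9,8.15,4
CoGH,X_laevis,Nematocera,terrestrial,65,19.39,19
CoGH,X_laevis,Neuroptera,terrestrial,1,0,1
CoGH,X_laevis,Psocoptera,terrestrial,0,0,0
CoGH,X_laevis,Trichoptera,benthos,14,55.18,7
CoGH,X_laevis,Zygoptera,nekton,24,390.33,15
CoGH,X_laevis,Zygentoma,terrestrial,0,0,0
CoGH,X_laevis,Amphipoda,nekton,43,416.45,10
CoGH,X_laevis,Daphnia,zooplankton,0,0,0
CoGH,X_laevis,Ostracoda,benthos,586,88.87,34
CoGH,X_laevis,Aranae,terrestrial,0,0,0
CoGH,X_laevis,Acari,nekton,139,4.61,28
CoGH,X_laevis,Scorpiones,terrestrial,0,0,0
CoGH,X_laevis,Anura,nekton,68,12368.1,49
CoGH,X_gilli,Anisoptera,nekton,11,343.08,6
CoGH,X_gilli,Brachycera,terrestrial,0,0,0
CoGH,X_gilli,Coleoptera,nekton,30,195.34,22
CoGH,X_gilli,Ephemeroptera,benthos,3,0.16,3
CoGH,X_gilli,Heteroptera,nekton,1,0.70,1
CoGH,X_gilli,Hymenoptera,terrestrial,3,0,3
CoGH,X_gilli,Nematocera,terrestrial,23,7.89,15
CoGH,X_gilli,Neuroptera,terrestrial,0,0,0
CoGH,X_gilli,Psocoptera,terrestrial,0,0,0
CoGH,X_gilli,Trichoptera,benthos,40,94.52,23
CoGH,X_gilli,Zygoptera,nekton,113,1983.17,37
CoGH,X_gilli,Zygentoma,terrestrial,0,0,0
CoGH,X_gilli,Amphipoda,nekton,497,1463.16,29
CoGH,X_gilli,Daphnia,zooplankton,493,91.84,6
CoGH,X_gilli,Ostracoda,benthos,352,53.38,25
CoGH,X_gilli,Aranae,terrestrial,0,0,0
CoGH,X_gilli,Acari,nekton,51,1.37,8
CoGH,X_gilli,Scorpiones,terrestrial,0,0,0
CoGH,X_gilli,Anura,nekton,24,4365.2,22
Kleinmond,environment,Blattodea,terrestrial,0,0,NA
Kleinmond,environment,Brachycera,terrestrial,0,0,NA
Kleinmond,environment,Coleoptera,nekton,260,4.45,NA
Kleinmond,environment,Collembola,terrestrial,0,0,NA
Kleinmond,environment,Ephemeroptera,benthos,9,0.08,NA
Kleinmond,environment,Heteroptera,nekton,166,1.16,NA
Kleinmond,environment,Hymenoptera,terrestrial,1,0,NA
Kleinmond,environment,Nematocera,terrestrial,2,0,NA
Kleinmond,environment,Sternorrhyncha,terrestrial,0,0,NA
Kleinmond,environment,Thysanoptera,terrestrial,0,0,NA
Kleinmond,environment,Trichoptera,benthos,0,0,NA
Kleinmond,environment,Zygoptera,nekton,0,0,NA
Kleinmond,environment,Amphipoda,nekton,496,0.93,NA
Kleinmond,environment,Daphnia,zooplankton,1,0,NA
Kleinmond,environment,Ostracoda,benthos,0,0,NA
Kleinmond,environment,Acari,nekton,11,0.03,NA
Kleinmond,environment,Aranae,terrestrial,0,0,NA
Kleinmond,environment,Pseudoscorpiones,terrestrial,1,0,NA
Kleinmond,environment,Annelida,benthos,0,0,NA
Kleinmond,environment,Anura,nekton,776,93.35,NA
Kleinmond,X_laevis,Blattodea,terrestrial,0,0,0
Kleinmond,X_laevis,Brachycera,terrestrial,1,0,1
Kleinmond,X_laevis,Coleoptera,nekton,65,1053.55,33
Kleinmond,X_laevis,Collembola,terrestrial,0,0,0
Kleinmond,X_laevis,Ephemeroptera,benthos,0,0,0
Kleinmond,X_laevis,Heteroptera,nekton,22,231.21,11
Kleinmond,X_laevis,Hymenoptera,terrestrial,0,0,0
Kleinmond,X_laevis,Nematocera,terrestrial,9,5.55,6
Kleinmond,X_laevis,Sternorrhyncha,terrestrial,0,0,0
Kleinmond,X_laevis,Thysanoptera,terrestrial,0,0,0
Kleinmond,X_laevis,Trichoptera,benthos,3,2.08,2
Kleinmond,X_laevis,Zygoptera,nekton,1,24.05,1
Kleinmond,X_laevis,Amphipoda,nekton,6,18.09,6
Kleinmond,X_laevis,Daphnia,zooplankton,440,1115.18,4
Kleinmond,X_laevis,Ostracoda,benthos,1,0.15,1
Kleinmond,X_laevis,Acari,nekton,1,1.41,1
Kleinmond,X_laevis,Aranae,terrestrial,0,0,0
Kleinmond,X_laevis,Pseudoscorpiones,terrestrial,0,0,0
Kleinmond,X_laevis,Annelida,benthos,0,0,0
Kleinmond,X_laevis,Anura,nekton,1131,12692.76,66
Kleinmond,X_gilli,Blattodea,terrestrial,2,62.38,1
Kleinmond,X_gilli,Brachycera,terrestrial,0,0,0
Kleinmond,X_gilli,Coleoptera,nekton,123,1127.53,41
Kleinmond,X_gilli,Collembola,terrestrial,1,0.07,1
Kleinmond,X_gilli,Ephemeroptera,benthos,0,0,0
Kleinmond,X_gilli,Heteroptera,nekton,12,65.84,7
Kleinmond,X_gilli,Hymenoptera,terrestrial,0,0,0
Kleinmond,X_gilli,Nematocera,terrestrial,14,113.53,10
Kleinmond,X_gilli,Sternorrhyncha,terrestrial,1,0.29,1
Kleinmond,X_gilli,Thysanoptera,terrestrial,1,0.05,1
Kleinmond,X_gilli,Trichoptera,benthos,6,11.29,4
Kleinmond,X_gilli,Zygoptera,nekton,0,0,0
Kleinmond,X_gilli,Amphipoda,nekton,32,590.05,13
Kleinmond,X_gilli,Daphnia,zooplankton,235,581.89,15
Kleinmond,X_gilli,Ostracoda,benthos,23,3.49,10
Kleinmond,X_gilli,Acari,nekton,4,7.54,3
Kleinmond,X_gilli,Aranae,terrestrial,1,0.43,1
Kleinmond,X_gilli,Pseudoscorpiones,terrestrial,0,0,0
Kleinmond,X_gilli,Annelida,benthos,1,485.36,1
Kleinmond,X_gilli,Anura,nekton,412,9697.35,63
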