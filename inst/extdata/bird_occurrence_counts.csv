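species,museum,field
Cacicus melanicterus,135,62
Chlorostilbon auriceps,61,23
Deltarhynchus flammulatus,26,26
Granatellus venustus,48,29
Melanerpes chrysogenys,196,87
Ortalis poliocephala,41,58
Passerina leclancherii,117,78
Polioptila nigriceps,38,12
Pheugopedius felix,123,92
Thryophilus sinaloa,151,92
Trogon citreolus,146,70
Vireo hypochryseus,106,62
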