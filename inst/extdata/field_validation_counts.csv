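species,site_total,site_true,site_false,buffer_total,buffer_true,buffer_false
Cacicus melanicterus,62,35,27,150,86,64
Chlorostilbon auriceps,23,15,8,63,47,16
Deltarhynchus flammulatus,26,22,4,67,56,11
Granatellus venustus,29,20,9,75,57,18
Melanerpes chrysogenys,87,58,29,197,134,63
Ortalis poliocephala,58,39,19,156,102,54
Passerina leclancherii,78,50,28,184,121,63
Polioptila nigriceps,12,6,6,28,15,13
Pheugopedius felix,92,61,31,197,139,58
Thryophilus sinaloa,92,60,32,187,126,61
Trogon citreolus,70,49,21,170,112,58
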