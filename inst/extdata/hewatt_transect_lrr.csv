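group,taxon,common_name,range_class,lrr,ci_low,ci_high
Anthozoans,Anthopleura sola,Anemone,southern,4.7,4.6,4.7
Anthozoans,Anthopleura xanthogrammica,Anemone,coastwide,-2.8,-3.1,-2.5
Anthozoans,Corynactis californica,Anemone,coastwide,2.4,1.3,3.5
Bivalves,Mytilus californianus,Mussel,coastwide,-2,-3.1,-0.9
Crustaceans,Balanus glandula,Barnacle,coastwide,1.8,0.7,3
Crustaceans,Chthamalus dalli/fissus,Barnacle,uncertain,5.1,3.5,6.7
Crustaceans,Pachycheles rudis,Crab,coastwide,-5,-5.4,-4.6
Crustaceans,Pachygrapsus crassipes,Crab,coastwide,-1.5,-2,-1.1
Crustaceans,Petrolisthes cinctipes,Crab,coastwide,-3.6,-4.1,-3.1
Crustaceans,Pugettia producta,Crab,coastwide,-2.2,-2.5,-1.8
Crustaceans,Pugettia richii,Crab,coastwide,0.9,0.5,1.2
Crustaceans,Tetraclita rubescens,Barnacle,southern,3.4,2.3,4.4
Echinoderms,Amphipholis squamata,Brittle star,coastwide,-4.5,-4.6,-4.4
Echinoderms,Leptasterias spp.,Sea star,uncertain,-2.3,-2.6,-1.9
Echinoderms,Patiria miniata,Sea star,coastwide,0.7,0.3,1
Echinoderms,Pisaster ochraceus,Sea star,coastwide,-2.5,-2.8,-2.3
Echinoderms,Strongylocentrotus purpuratus,Sea urchin,coastwide,-2.4,-3,-1.8
Gastropods,Acanthinucella punctulata,Snail,southern,1.8,1.4,2.3
Gastropods,Acmaea mitra,Limpet,coastwide,-1.7,-2.2,-1.3
Gastropods,Alia carinata,Snail,coastwide,-5.1,-5.6,-4.6
Gastropods,Amphissa versicolor,Snail,coastwide,-2.7,-3.2,-2.2
Gastropods,Californiconus californicus,Snail,southern,0.7,0.2,1.2
Gastropods,Calliostoma ligatum,Snail,coastwide,0.4,0.1,0.7
Gastropods,Crepidula adunca,Snail,coastwide,0.5,0.3,0.7
Gastropods,Epitonium tinctum,Snail,coastwide,0.6,0.3,0.9
Gastropods,Fissurella volcano,Keyhole limpet,southern,-0.4,-0.7,-0.1
Gastropods,Hesperaptyxis luteopictus,Snail,southern,0.5,0.2,0.8
Gastropods,Lacuna marmorata,Snail,coastwide,1.8,0.9,2.7
Gastropods,Littorina plena/scutulata,Snail,coastwide,0.5,-0.1,1
Gastropods,Lottia instabilis,Limpet,coastwide,0.6,0,1.3
Gastropods,Lottia limatula,Limpet,coastwide,-2.1,-2.6,-1.5
Gastropods,Lottia scabra,Limpet,coastwide,1.1,0.4,1.9
Gastropods,Lottia scutum,Limpet,coastwide,-5.6,-5.9,-5.3
Gastropods,Paciocinebrina circumtexta,Snail,coastwide,2.9,2.6,3.2
Gastropods,Tectura paleacea,Limpet,coastwide,0.6,0.1,1.1
Gastropods,Tegula brunnea,Snail,coastwide,3.9,3.5,4.2
Gastropods,Tegula funebralis,Snail,coastwide,1.3,1.1,1.6
Gastropods,Tegula pulligo,Snail,coastwide,0.4,0,0.8
Gastropods,Thylacodes squamigerus,Snail,southern,4.2,3.7,4.8
Platyhelminths,Notocomplana acticola,Flatworm,coastwide,0.3,-0.1,0.7
Polychaetes,Halosydna brevisetosa,Segmented worm,coastwide,-4.3,-4.6,-4
Polyplacophorans,Mopalia muscosa,Chiton,coastwide,-1.4,-1.8,-1
Polyplacophorans,Nuttallina californica,Chiton,coastwide,1.2,0.7,1.6
Polyplacophorans,Tonicella lineata,Chiton,coastwide,0.2,-0.1,0.4
Poriferans,Haliclona sp. A,Sponge,southern,0.5,0,1
Sipunculids,Phascolosoma agassizii,Peanut worm,coastwide,-4.3,-4.6,-4
Tunicates,Clavelina huntsmani,Sea squirt,coastwide,-1.5,-2.5,-0.4
Tunicates,Polyclinum planum,Sea squirt,southern,-0.1,-0.6,0.3
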