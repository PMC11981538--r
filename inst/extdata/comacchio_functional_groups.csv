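taxon,functional_group,category,pre,post
Alitta succinea,Surface Deposit Feeders,animal,TRUE,FALSE
Bivalvia larvae,Suspension Feeders,animal,TRUE,FALSE
Chironomus salinarius,Subsurface Deposit Feeders,animal,TRUE,FALSE
Dicentrarchus labrax,Dicentrarchus labrax,animal,TRUE,FALSE
Haminoea hydatis,Surface Deposit Feeders,animal,TRUE,FALSE
Hydrobia sp.,Surface Deposit Feeders,animal,TRUE,FALSE
Idotea balthica,Scrapers,animal,TRUE,FALSE
Lamprothamnium papulosum,Lamprothamnium papulosum,producer,TRUE,FALSE
Littorina sp.,Grazers,animal,TRUE,FALSE
Maja squinado,Maja squinado,animal,TRUE,FALSE
Palaemon elegans,Shrimp,animal,TRUE,FALSE
Platichthys flesus,Flatfish,animal,TRUE,FALSE
Polychaeta larvae,Surface Deposit Feeders,animal,TRUE,FALSE
Polychaeta mobile,Benthic Predators,animal,TRUE,FALSE
Ruppia cirrhosa,Ruppia cirrhosa,producer,TRUE,FALSE
Small invertebrate larvae,Filter Feeders,animal,TRUE,FALSE
Solea solea,Flatfish,animal,TRUE,FALSE
Tritia neritea,Grazers,animal,TRUE,FALSE
Upogebia pusilla,Upogebia pusilla,animal,TRUE,FALSE
Acartia,Surface Deposit Feeders,animal,FALSE,TRUE
Ardea alba,Birds,animal,FALSE,TRUE
Ardea cinerea,Birds,animal,FALSE,TRUE
Balanidae sp.,Suspension Feeders,animal,FALSE,TRUE
Chironomidae,Subsurface Deposit Feeders,animal,FALSE,TRUE
Ciliata,Surface Deposit Feeders,animal,FALSE,TRUE
Crangon crangon,Shrimp,animal,FALSE,TRUE
Cumacea sp.,Grazers,animal,FALSE,TRUE
Diatom,Diatom,producer,FALSE,TRUE
Dinoflagellata,Dinoflagellata,producer,FALSE,TRUE
Egretta garzetta,Birds,animal,FALSE,TRUE
Engraulis encrasicolus,Engraulis encrasicolus,animal,FALSE,TRUE
Hydrobiidae,Surface Deposit Feeders,animal,FALSE,TRUE
Malacostraca,Grazers,animal,FALSE,TRUE
Mysida,Grazers,animal,FALSE,TRUE
Nanocyanobacteria,Nanocyanobacteria,cyanobacteria,FALSE,TRUE
Nemertea,Benthic Predators,animal,FALSE,TRUE
Nereididae sp.,Surface Deposit Feeders,animal,FALSE,TRUE
Palaemon sp.,Shrimp,animal,FALSE,TRUE
Phalacrocorax carbo,Birds,animal,FALSE,TRUE
Phalacrocorax pygmaeus,Birds,animal,FALSE,TRUE
Picocyanobacteria,Picocyanobacteria,cyanobacteria,FALSE,TRUE
Podiceps cristatus,Birds,animal,FALSE,TRUE
Podiceps nigricollis,Birds,animal,FALSE,TRUE
Polychaeta,Surface Deposit Feeders,animal,FALSE,TRUE
Shrimp,Shrimp,animal,FALSE,TRUE
Spionidae,Benthic Predators,animal,FALSE,TRUE
Sterna hirundo,Birds,animal,FALSE,TRUE
Sterna sandvicensis,Birds,animal,FALSE,TRUE
Syllidae sp.,Surface Deposit Feeders,animal,FALSE,TRUE
Tanaidacea sp.,Grazers,animal,FALSE,TRUE
Turbellaria,Benthic Predators,animal,FALSE,TRUE
Zoea larvae,Grazers,animal,FALSE,TRUE
Actiniaria,Actiniaria,animal,TRUE,TRUE
Amphipoda,Scrapers,animal,TRUE,TRUE
Anguilla anguilla,Anguilla anguilla,animal,TRUE,TRUE
Anguilla anguilla Juvenile,Anguilla anguilla,animal,TRUE,TRUE
Aphanius fasciatus,Aphanius fasciatus,animal,TRUE,TRUE
Atherina boyeri,Atherina boyeri,animal,TRUE,TRUE
Bivalvia,Suspension Feeders,animal,TRUE,TRUE
Carcinus aestuarii,Carcinus aestuarii,animal,TRUE,TRUE
Chelon auratus,Mugil spp.,animal,TRUE,TRUE
Chelon ramada,Mugil spp.,animal,TRUE,TRUE
Chelon saliens,Mugil spp.,animal,TRUE,TRUE
Copepoda,Copepoda,animal,TRUE,TRUE
Crustacea,Scrapers,animal,TRUE,TRUE
Detritus,Detritus,detritus,TRUE,TRUE
Gammarus sp.,Scrapers,animal,TRUE,TRUE
Gastropoda,Grazers,animal,TRUE,TRUE
Gobidae,Gobidae,animal,TRUE,TRUE
Monocorophium insidiosum,Surface Deposit Feeders,animal,TRUE,TRUE
Mugil cephalus,Mugil spp.,animal,TRUE,TRUE
Oligochaeta,Subsurface Deposit Feeders,animal,TRUE,TRUE
Polychaeta sedentary,Surface Deposit Feeders,animal,TRUE,TRUE
Rotifera,Filter Feeders,animal,TRUE,TRUE
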