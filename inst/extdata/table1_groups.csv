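# Group-level mean isotope ratios (per mil), sample counts and published
# trophic positions for the Angolan margin cold-water coral reef community.
# reported_tp / reported_tp_sd are the published values (fauna only).
# Transcription notes:
#  - Gorg mean_d13C restored to -17.35: the sign was dropped in the published
#    table; every other faunal d13C is negative and -17.35 is physically
#    required for marine tissue.
#  - D_pert reported_tp_sd stored as 0.40: printed "04.0", a digit
#    transposition (1.37 / 3.4 = 0.40).
label,taxon,compartment,depth_m,n,mean_d15N,sd_d15N,mean_d13C,sd_d13C,reported_tp,reported_tp_sd
Sed259,Sediment 259 m,sediment,259,1,5.90,,-21.08,,,
Sed345,Sediment 345 m,sediment,345,1,6.19,,-20.84,,,
SPOMtrap342,Sediment trap material 342 m,spom_trap,342,1,5.32,,-21.73,,,
SPOMtrap526,Sediment trap material 526 m,spom_trap,526,1,5.61,,-21.40,,,
SPOM342,Suspended Particulate Organic Matter 342 m,spom,342,20,3.97,0.80,-22.46,0.34,,
SPOM532,Suspended Particulate Organic Matter 532 m,spom,532,24,2.00,1.48,-21.89,0.47,,
Aph,Aphrocallistes sp.,fauna,,3,20.83,2.59,-19.40,0.19,5.88,0.76
Sym,Sympagella sp.,fauna,,1,21.31,,-18.83,,6.02,
Dem,Demospongiae sp.,fauna,,1,19.58,,-19.96,,5.51,
Hex,Hexactinellida sp.,fauna,,1,21.90,,-17.20,,6.20,
Por,Porifera indet. sp.,fauna,,1,17.33,,-18.20,,4.85,
Actin,Actiniaria spp.,fauna,,3,12.37,1.71,-19.13,0.08,3.39,0.50
Cal,Callogorgia sp.,fauna,,1,13.45,,-17.25,,3.71,
Clav,Clavularia sp.,fauna,,3,13.26,0.62,-19.37,0.12,3.66,0.18
Eun,Eunicella sp.,fauna,,2,13.21,0.44,-19.04,0.05,3.64,0.13
Gorg,Gorgoniidae spp.,fauna,,4,13.60,0.83,-17.35,2.02,3.75,0.24
Hyd,Hydrozoa,fauna,,1,11.94,,-18.81,,3.27,
D_pert,Desmophyllum pertusum,fauna,,4,11.56,1.37,-19.77,1.00,3.16,0.40
Madr,Madrepora oculata,fauna,,2,10.52,1.07,-19.70,1.88,2.85,0.32
Par,Paramuricea sp.,fauna,,3,12.83,0.48,-19.26,0.09,3.52,0.14
Parant,Parantipathes sp.,fauna,,1,13.51,,-19.11,,3.73,
Spi,Spinimuricea sp.,fauna,,1,13.96,,-17.79,,3.86,
Mun,Munida sp.,fauna,,2,13.41,0.33,-17.99,0.59,3.70,0.10
E_nor,Eunice norvegica,fauna,,2,14.75,0.23,-15.39,0.69,4.10,0.07
Poly,Polynoidae sp.,fauna,,1,14.00,,-18.28,,3.87,
Ast,Asteroidea spp.,fauna,,3,17.04,4.10,-14.09,0.20,4.77,1.21
Ech,Echinus sp.,fauna,,3,14.88,1.49,-12.81,1.65,4.13,0.44
Oph,Ophiuroidea,fauna,,2,13.18,0.52,-13.65,1.24,3.63,0.15
Mycto,Myctophidae sp.,fauna,,3,12.35,0.38,-18.98,1.19,3.39,0.11
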