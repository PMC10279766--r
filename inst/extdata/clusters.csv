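# Published k-means guild memberships (k = 4) for the Angolan reef groups.
# Cluster numbering follows ascending mean d15N: 1 = particulate organic
# matter pools, 2 = suspension feeders, 3 = predators/detritivores,
# 4 = sponges.
label,cluster
Sed259,1
Sed345,1
SPOMtrap342,1
SPOMtrap526,1
SPOM342,1
SPOM532,1
Actin,2
Cal,2
Clav,2
Eun,2
Gorg,2
Hyd,2
D_pert,2
Madr,2
Par,2
Parant,2
Spi,2
Mun,2
Poly,2
Mycto,2
Ast,3
Ech,3
Oph,3
E_nor,3
Aph,4
Sym,4
Dem,4
Hex,4
Por,4
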