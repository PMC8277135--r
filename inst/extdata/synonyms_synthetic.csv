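raw,canonical
polychaetes,mobile infauna
worms,mobile infauna
annelids,mobile infauna
bivalves,burrowing infauna
clams,burrowing infauna
mussels,sessile epifauna
crustaceans,mobile epifauna
microbes,bacterial communities
turbidity,background turbidity
suspended solids,sediment dispersal in the water column
toxic substances,contaminants in sediment
seafloor morphology,modification of seafloor topography
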