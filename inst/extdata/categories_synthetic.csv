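label,category
mining intensity,operational factor
depth of extracted sediment,operational factor
processing return technique,operational factor
volume of extraction,operational factor
water depth at extraction site,operational factor
duration of operation,operational factor
mining vessel operation,operational factor
extraction pattern,operational factor
nodule removal,pressure
modification of seafloor substrate type,pressure
modification of seafloor topography,pressure
sediment dispersal in the water column,pressure
sediment dispersal near seafloor,pressure
release of nutrients from the sediment,pressure
release of toxic substances from the sediment,pressure
underwater noise,pressure
sediment type,environmental condition
contaminants in sediment,environmental condition
grain size,environmental condition
organic matter content,environmental condition
oxygen conditions,environmental condition
near-bottom currents,environmental condition
water column stratification,environmental condition
salinity,environmental condition
temperature,environmental condition
background turbidity,environmental condition
nutrient status,environmental condition
sediment compaction,environmental condition
pore water composition,environmental condition
light availability,environmental condition
sessile epifauna,biological component
mobile epifauna,biological component
mobile infauna,biological component
burrowing infauna,biological component
filter feeders,biological component
deposit feeders,biological component
predatory invertebrates,biological component
meiofauna,biological component
bacterial communities,biological component
phytoplankton,biological component
zooplankton,biological component
macrophytes,biological component
demersal fish,biological component
pelagic fish,biological component
fish eggs and larvae,biological component
marine mammals,biological component
seabirds,biological component
benthic food availability,biological component
primary production,biological component
benthic habitat structure,biological component
species richness,biological component
community biomass,biological component
reproductive success,biological component
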