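scenario A
  set mining_intensity = 75% removed
  set depth_of_extracted_sediment = 11-30 cm
scenario B
  set mining_intensity = 50% removed
  set depth_of_extracted_sediment = 11-30 cm
  evidence contaminant_release = significant
scenario S01
  set mining_intensity = 50% removed
  set depth_of_extracted_sediment = <10 cm
  set processing_return_technique = at the surface
scenario S02
  set mining_intensity = 75% removed
  set depth_of_extracted_sediment = <10 cm
  set processing_return_technique = at the surface
scenario S03
  set mining_intensity = 100% removed
  set depth_of_extracted_sediment = <10 cm
  set processing_return_technique = at the surface
scenario S04
  set mining_intensity = 50% removed
  set depth_of_extracted_sediment = 11-30 cm
  set processing_return_technique = at the surface
scenario S05
  set mining_intensity = 75% removed
  set depth_of_extracted_sediment = 11-30 cm
  set processing_return_technique = at the surface
scenario S06
  set mining_intensity = 100% removed
  set depth_of_extracted_sediment = 11-30 cm
  set processing_return_technique = at the surface
scenario S07
  set mining_intensity = 50% removed
  set depth_of_extracted_sediment = >30 cm
  set processing_return_technique = at the surface
scenario S08
  set mining_intensity = 75% removed
  set depth_of_extracted_sediment = >30 cm
  set processing_return_technique = at the surface
scenario S09
  set mining_intensity = 100% removed
  set depth_of_extracted_sediment = >30 cm
  set processing_return_technique = at the surface
scenario S10
  set mining_intensity = 50% removed
  set depth_of_extracted_sediment = <10 cm
  set processing_return_technique = at the bottom
scenario S11
  set mining_intensity = 75% removed
  set depth_of_extracted_sediment = <10 cm
  set processing_return_technique = at the bottom
scenario S12
  set mining_intensity = 100% removed
  set depth_of_extracted_sediment = <10 cm
  set processing_return_technique = at the bottom
scenario S13
  set mining_intensity = 50% removed
  set depth_of_extracted_sediment = 11-30 cm
  set processing_return_technique = at the bottom
scenario S14
  set mining_intensity = 75% removed
  set depth_of_extracted_sediment = 11-30 cm
  set processing_return_technique = at the bottom
scenario S15
  set mining_intensity = 100% removed
  set depth_of_extracted_sediment = 11-30 cm
  set processing_return_technique = at the bottom
scenario S16
  set mining_intensity = 50% removed
  set depth_of_extracted_sediment = >30 cm
  set processing_return_technique = at the bottom
scenario S17
  set mining_intensity = 75% removed
  set depth_of_extracted_sediment = >30 cm
  set processing_return_technique = at the bottom
scenario S18
  set mining_intensity = 100% removed
  set depth_of_extracted_sediment = >30 cm
  set processing_return_technique = at the bottom
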