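site_id,site_type,area_ha,elevation_m,slope_deg,aspect_deg,cover_type
demo1,stand,42,2231,9,165,ponderosa
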