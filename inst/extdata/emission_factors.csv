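class,tier,ef_mean,ef_low,ef_high,n_sites,source,published_emission_t
cutover,T1,2.8,1.1,4.2,,IPCC Wetlands Supplement (2013) Tier-1 default,181157
cutaway,T1,2.8,1.1,4.2,,IPCC Wetlands Supplement (2013) Tier-1 default,152046
forestry,T1,2.6,2.0,3.3,,IPCC Wetlands Supplement (2013) Tier-1 default,302710
grassland,T1,5.3,3.7,6.9,,IPCC Wetlands Supplement (2013) Tier-1 default,1293730
cutover,T2,1.21,0.4,2.0,3,Irish peat-extraction flux case studies,102871
cutaway,T2,1.59,1.2,2.0,4,Irish peat-extraction flux case studies,65705
forestry,T2,1.68,1.04,2.32,8,Irish drained afforested peatland sites,195597
grassland,T2,1.3,0.04,2.55,3,Irish drained grassland flux case studies,317330
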