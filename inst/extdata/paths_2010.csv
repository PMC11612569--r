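from,to,coef,source
Topography,HQ,0.18,published
HumanDisturbance,HQ,-0.13,published
NDVI,HQ,0.20,nominal_mediator_coefficient
Topography,NDVI,0.65,reconstructed_from_channel_product_0.13
Topography,HumanDisturbance,-0.07692308,reconstructed_from_channel_product_0.01
HumanDisturbance,NDVI,-0.15,reconstructed_from_channel_product_-0.03
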