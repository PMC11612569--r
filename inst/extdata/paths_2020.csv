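from,to,coef,source
Topography,HQ,0.36,published
NDVI,HQ,0.14,published
Climate,HQ,-0.10,published
Climate,NDVI,-0.14285714,reconstructed_from_channel_product_-0.02
HumanDisturbance,HQ,-0.16,published
HumanDisturbance,NDVI,-0.14285714,reconstructed_from_channel_product_-0.02
Topography,Climate,0.58333333,reconstructed_from_channel_product_-0.07
Topography,HumanDisturbance,-0.10,nominal_mediator_coefficient
Topography,NDVI,0.37142857,reconstructed_from_channel_product_0.07
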