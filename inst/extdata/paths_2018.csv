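from,to,coef,source
Topography,HQ,0.38,published
Topography,NDVI,0.44,published
Topography,HumanDisturbance,-0.13,published
Topography,Climate,0.86666667,reconstructed_from_channel_product_-0.13
Climate,HQ,-0.17,published
Climate,NDVI,0.20,reconstructed_from_channel_product_0.02
HumanDisturbance,HQ,-0.20,published
HumanDisturbance,NDVI,-0.30,reconstructed_from_channel_product_-0.03
NDVI,HQ,0.10,reconstructed_from_channel_product_0.07
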