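from,to,coef,source
Topography,HQ,0.03,published
NDVI,HQ,0.09,published
Climate,HQ,0.21,published
HumanDisturbance,HQ,-0.12,published
Topography,NDVI,0.76666667,reconstructed_from_channel_product_0.069
Topography,HumanDisturbance,-0.01666667,reconstructed_from_channel_product_0.002
HumanDisturbance,NDVI,-0.11111111,reconstructed_from_channel_product_-0.01
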