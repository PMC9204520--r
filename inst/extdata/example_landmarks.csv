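landmark,distance_m
pelvis_width,0.32852
femur_length,0.4214
tibia_length,0.42312
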