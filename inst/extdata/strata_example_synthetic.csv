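stratum_id,weight,serves_fruit,serves_veg,serves_grains,serves_meat,serves_dairy,serves_discretionary_upper,eer_kj
m_04_08,0.06,1.5,4.5,4,1.5,2,1,6500
f_04_08,0.06,1.5,4.5,4,1.5,2,1,6000
m_09_18,0.10,2,5.5,7,2.5,3.5,3,9500
f_09_18,0.10,2,5,7,2.5,3.5,2.5,8000
m_19_50,0.24,2,6,6,3,2.5,3,10500
f_19_50,0.24,2,5,6,2.5,2.5,2.5,8500
m_51plus,0.10,2,5.5,6,2.5,2.5,2.5,9000
f_51plus,0.10,2,5,4,2,4,2.5,7500
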