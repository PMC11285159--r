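((((Pphilander_LakeChila:0.5,Pphilander_MbuluCreek:0.5):1.5,Pphilander_Thamalakane:2.0,(Pphilander_LakeMweru:1.0,Pnicholsi:1.0):1.0,(Pmulticolor_victoriae:0.5,Pmulticolor_multicolor:0.5):1.5):3.0,Lufubuchromis_relictus:5.0):1.5,Thoracochromis_callichromus:6.5);
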