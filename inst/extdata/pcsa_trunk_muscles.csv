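muscle,base,female_specific
multifidus,14.07,9.49
erector_spinae,27.89,16.14
quadratus_lumborum,4.41,2.44
psoas_major,14.63,10.67
internal_oblique,6.24,6.30
external_oblique,6.24,7.08
rectus_abdominis,7.80,6.37
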