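# Feeding-load physics parameters.
# shake.amplitude_rad has no published value; 0.5 rad is a worked-example
# choice and must be set explicitly by the user for shake magnitudes.
shake:
  frequency_hz: 4
  amplitude_rad: 0.5
  prey_mass_multiplier: 3
twist:
  rotation_rad: 6.283185307179586
  duration_s: 0.5
  body_mass_multiplier: 50
muscle:
  specific_tension_mpa: 0.3
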