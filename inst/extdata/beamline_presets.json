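{
  "id29_feb2024": {
    "description": "Fourth-generation synchrotron SSX endstation, Feb 2024 run",
    "flux_at_ref": 1.6e15,
    "ref_current": 200,
    "current": 68,
    "exposure": 9e-05,
    "photon_energy": 11.56,
    "beam_area": 8,
    "attenuation_transmission": 1,
    "rate_hz": 231.25,
    "fast_axis": "x",
    "diffraction_weighted_dose_mgy": 0.88
  },
  "cristallina_jun2023": {
    "description": "XFEL fixed-target endstation, Jun 2023 run",
    "photons_per_pulse": 5.44e10,
    "exposure": 3e-14,
    "photon_energy": 12.04,
    "beam_area": 25,
    "rate_hz": 100,
    "fast_axis": "y",
    "diffraction_weighted_dose_mgy": 0.20
  },
  "cristallina_sep2023": {
    "description": "XFEL fixed-target endstation, Sep 2023 run",
    "photons_per_pulse": 6.22e10,
    "exposure": 2.5e-14,
    "photon_energy": 12.04,
    "beam_area": 25,
    "rate_hz": 100,
    "fast_axis": "y",
    "diffraction_weighted_dose_mgy": 0.18
  }
}
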