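sigma_v:
  value: 1.0
  unit: mm
sigma_p:
  value: 15.0
  unit: mm
sigma_tv:
  value: 20.0
  unit: ms
sigma_tt:
  value: 20.0
  unit: ms
mu_x:
  value: 0.0
  unit: mm
sigma_x:
  value: 3.56108300643601959e+44
  unit: mm
mu_t:
  value: 0.0
  unit: ms
sigma_t:
  value: 3.56108300643601959e+44
  unit: ms
p_common: 0.5
include_temporal: yes
provenance: 'prior widths calibrated by calibrate_prior_width(target_mm = 300, params_template
  = rhi_params()): noise-free common-cause posterior = 0.5 at a 300 mm hand separation
  with synchronous timing'
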