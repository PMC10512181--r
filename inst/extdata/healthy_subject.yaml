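# Normative healthy 70-kg adult: subject block of the model configuration.
# Missing entries (cardiac, circulation) fall back to package defaults.
subject:
  SBP: 120.0        # mean systolic arterial pressure, mmHg
  DBP: 80.0         # mean diastolic arterial pressure, mmHg
  EDP_LV: 5.0       # LV end-diastolic pressure, mmHg
  ESV_LV: 50.0      # LV end-systolic volume, mL
  EDV_LV: 125.0     # LV end-diastolic volume, mL
  ESP_RV: 25.0      # RV end-systolic pressure, mmHg
  ESV_RV: 50.0      # RV end-systolic volume, mL
  EDV_RV: 125.0     # RV end-diastolic volume, mL
  TBV: 5000.0       # total blood volume, mL
  HR: 60.0          # heart rate, bpm
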