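label: Croatia nationwide CMM 2022-2024 (published_tables)
years:
- 2022
- 2023
- 2024
mode: published_tables
population:
  dmt2_on_medication: 240398.0
  combined_on_medication: 765687.0
  growth_rate: 0.01
  polypharmacy_fraction: 0.84999999999999998
  provenance:
    national_population: 4087934.0
    dmt2_prevalence: 0.0774
    dmt2_on_medication_fraction: 0.76000000000000001
    cvd_prevalence: 0.26019999999999999
    cvd_on_medication_fraction: 0.90000000000000002
enrollment_fractions:
- 0.05
- 0.07000000000000001
- 0.09
costs:
  visits_per_patient_year: 2.0
  visit_capacity_per_pharmacist_year: 2904.0
  annual_cost_per_pharmacist: 28000.0
  training_cost_per_pharmacist: 200.0
  therapy_cost_per_patient_year: 37.47330000000000183
services:
- name: Clinic outpatient visit avoided
  avoided_count: 10313.0
  adjustment: 0.69999999999999996
  encounters_base: 33706.0
  unit_price: 10.40000000000000036
- name: Specialty office visit avoided
  avoided_count: 1346.0
  adjustment: 1.0
  encounters_base: 33706.0
  unit_price: 18.92999999999999972
- name: Employee work days saved
  avoided_count: 277.0
  adjustment: 1.0
  encounters_base: 33706.0
  unit_price: 47.18999999999999773
- name: Laboratory service avoided
  avoided_count: 240.0
  adjustment: 1.0
  encounters_base: 33706.0
  unit_price: 8.09999999999999964
- name: Urgent care visit avoided
  avoided_count: 355.0
  adjustment: 1.0
  encounters_base: 33706.0
  unit_price: 54.13000000000000256
- name: Hospital admission avoided
  avoided_count: 41.0
  adjustment: 1.0
  encounters_base: 33706.0
  unit_price: 120.12999999999999545
- name: Nursing home admissions
  avoided_count: 3.0
  adjustment: 1.0
  encounters_base: 33706.0
  unit_price: 20.0
- name: Home health visit
  avoided_count: 1.0
  adjustment: 1.0
  encounters_base: 33706.0
  unit_price: 16.01999999999999957
events:
- event: Heart failure
  group: DMT2+CVD
  incidence_per_1000: 23.85999999999999943
  guideline_risk_reduction: 0.40000000000000002
  efficiency: 0.90000000000000002
  inpatient_cost: 1182.24000000000000909
  followup_cost: 1176.0
  device_cost: 2473.9499999999998181
- event: Heart failure
  group: CVD
  incidence_per_1000: 9.69999999999999929
  guideline_risk_reduction: 0.40000000000000002
  efficiency: 0.90000000000000002
  inpatient_cost: 1182.24000000000000909
  followup_cost: 1176.0
  device_cost: 2473.9499999999998181
- event: Stroke
  group: DMT2+CVD
  incidence_per_1000: 14.59999999999999964
  guideline_risk_reduction: 0.34999999999999998
  efficiency: 0.90000000000000002
  inpatient_cost: 1959.45000000000004547
  followup_cost: 1176.0
  device_cost: 0.0
- event: Stroke
  group: CVD
  incidence_per_1000: 7.70000000000000018
  guideline_risk_reduction: 0.34999999999999998
  efficiency: 0.90000000000000002
  inpatient_cost: 1959.45000000000004547
  followup_cost: 1176.0
  device_cost: 0.0
  override_risk_reduction: 0.004599
- event: Myocardial infarction - fatal
  group: DMT2+CVD
  incidence_per_1000: 18.0
  guideline_risk_reduction: 0.20000000000000001
  efficiency: 0.90000000000000002
  inpatient_cost: 864.78999999999996362
  followup_cost: 0.0
  device_cost: 0.0
- event: Myocardial infarction - fatal
  group: CVD
  incidence_per_1000: 8.69999999999999929
  guideline_risk_reduction: 0.20000000000000001
  efficiency: 0.90000000000000002
  inpatient_cost: 864.78999999999996362
  followup_cost: 0.0
  device_cost: 0.0
  override_risk_reduction: 0.00324
- event: Myocardial infarction - nonfatal
  group: DMT2+CVD
  incidence_per_1000: 27.80000000000000071
  guideline_risk_reduction: 0.20000000000000001
  efficiency: 0.90000000000000002
  inpatient_cost: 1806.20000000000004547
  followup_cost: 1176.0
  device_cost: 0.0
  override_unit_cost: 864.78999999999996362
- event: Myocardial infarction - nonfatal
  group: CVD
  incidence_per_1000: 13.0
  guideline_risk_reduction: 0.20000000000000001
  efficiency: 0.90000000000000002
  inpatient_cost: 1806.20000000000004547
  followup_cost: 1176.0
  device_cost: 0.0
  override_unit_cost: 864.78999999999996362
- event: Angina
  group: DMT2+CVD
  incidence_per_1000: 21.60000000000000142
  guideline_risk_reduction: 0.20000000000000001
  efficiency: 0.90000000000000002
  inpatient_cost: 1127.50999999999999091
  followup_cost: 1176.0
  device_cost: 0.0
  override_unit_cost: 864.78999999999996362
- event: Angina
  group: CVD
  incidence_per_1000: 14.59999999999999964
  guideline_risk_reduction: 0.20000000000000001
  efficiency: 0.90000000000000002
  inpatient_cost: 1127.50999999999999091
  followup_cost: 1176.0
  device_cost: 0.0
  override_unit_cost: 864.78999999999996362
- event: Revascularization - stenotic coronary arteries
  group: DMT2+CVD
  incidence_per_1000: 3.85000000000000009
  guideline_risk_reduction: 0.20000000000000001
  efficiency: 0.90000000000000002
  inpatient_cost: 1061.82999999999992724
  followup_cost: 1176.0
  device_cost: 0.0
  override_unit_cost: 864.78999999999996362
- event: Revascularization - stenotic coronary arteries
  group: CVD
  incidence_per_1000: 3.85000000000000009
  guideline_risk_reduction: 0.20000000000000001
  efficiency: 0.90000000000000002
  inpatient_cost: 1061.82999999999992724
  followup_cost: 1176.0
  device_cost: 0.0
  override_unit_cost: 864.78999999999996362
sensitivity_factors:
- 1.05000000000000004
- 0.94999999999999996
- 0.80000000000000004
- 0.59999999999999998

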