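# Care-model efficiency scenarios: named combinations of provision
# inputs and utilisation outputs, each giving one "point of view" on
# the relative technical efficiency of the small health areas.
# Eleven of the fifteen reference scenarios are enumerated variable by
# variable (S4, S6..S15); the remaining four (S1, S2, S3, S5) were never
# published as variable lists and are deliberately not invented here.
scenarios:
  - id: S4
    label: Day care health related
    input_vars: [TD1, TD41, ProfTotD1+D41, ProfPsychiD1+D41,
                 ProfPsychoDUED1+D41, PD1+D41]
    output_vars: [UD1, UD41]
  - id: S6
    label: Outpatient care
    input_vars: [TO8+O10, ProfPsychiO8+O10, ProfPsychoO8+O10,
                 ProfDUEO8+O10, ProfTotO8+O10]
    output_vars: [UPrevO8+O10, UIncO8+O10, UFrecO8+O10]
  - id: S7
    label: Placement capacity
    input_vars: [PR2, PR8+R11, PD1+D41, PD4other, PD4other+D2-D3]
    output_vars: [UDischargesR2, UStayR2, UPrevO8+O10, UFrecO8+O10]
  - id: S8
    label: Placement capacity health related
    input_vars: [PR2, PR4-R7, PD1, PD41]
    output_vars: [UDischargesR2, UStayR2, UReAdmissionR2, UPrevO8+O10,
                  UFrecO8+O10]
  - id: S9
    label: Workforce capacity health related
    input_vars: [ProfPsychiR2, ProfPsychoDUER2, ProfPsychiR4-R7,
                 ProfPsychoDUER4-R7, ProfTotD1+D41]
    output_vars: [UDischargesR2, UPrevO8+O10]
  - id: S10
    label: Workforce capacity total
    input_vars: [ProfTotR2, ProfTotR4-R7, ProfTotR8-R13, ProfTotD1+D41,
                 ProfTotD4+D2-D3, ProfTotO8+O10]
    output_vars: [UDischargesR2, UPrevO8+O10]
  - id: S11
    label: >-
      Combination of residential and day health related placement
      capacity and availability of outpatient care
    input_vars: [PR2, PR4-R7, PD1+D41, TO8+O10]
    output_vars: [UDischargesR2, UStayR2, UReAdmissionR2, UPrevO8+O10,
                  UFrecO8+O10]
  - id: S12
    label: >-
      Combination of hospital-community residential and day health
      related placement capacity and outpatient availability
    input_vars: [PR2, PR8-R13, PD1+D41, TO8+O10]
    output_vars: [UDischargesR2, UStayR2, UPrevO8+O10, UFrecO8+O10]
  - id: S13
    label: Placement capacity of acute residential, day and outpatient care
    input_vars: [PR2, PR8+R11, PR12, PD1+D41, PD4other+D2-D3]
    output_vars: [UDischargesR2, UReAdmissionR2, UPrevO8+O10,
                  UFrecO8+O10]
  - id: S14
    label: >-
      Combination of day and residential placement and workforce
      capacity of residential-outpatient care
    input_vars: [PR2, PR4-R7, PD1+D41, ProfPsychiR2, ProfTotR4-R7,
                 ProfTotO8+O10]
    output_vars: [UDischargesR2, UPrevO8+O10]
  - id: S15
    label: >-
      Combination of health-community residential placement capacity
      and workforce capacity of residential-outpatient care
    input_vars: [PR2-R7, ProfTotR2-R7, PR8-R13, ProfTotR8-R13,
                 ProfTotO8+O10]
    output_vars: [UDischargesR2, UReAdmissionR2, UPrevO8+O10]
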