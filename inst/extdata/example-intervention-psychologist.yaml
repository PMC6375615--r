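# Example meso-management intervention for a real regional dataset:
# reassigning one psychologist (1.0 full-time equivalent) from an
# outpatient service in one area to a day hospital in another.
# Edits are in "count" mode: head counts are converted to rates per
# 100,000 with each area's population when applied. The 1.0 FTE amount
# is a placeholder -- real specifications should state the actual
# fractions, and any secondary (causal) edits on areas served by the
# restructured service must be listed explicitly here as well.
id: EX-I1
description: >-
  Reassign one psychologist from outpatient care (Uribe) to the day
  hospital (Durango).
edits:
  - {dmu: Uribe, variable: ProfPsychoO8+O10, change: -1.0, mode: count,
     direction: decreasing}
  - {dmu: Uribe, variable: ProfTotO8+O10, change: -1.0, mode: count,
     direction: decreasing}
  - {dmu: Durango, variable: ProfPsychoDUED1+D41, change: 1.0,
     mode: count, direction: increasing}
  - {dmu: Durango, variable: ProfTotD1+D41, change: 1.0, mode: count,
     direction: increasing}
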