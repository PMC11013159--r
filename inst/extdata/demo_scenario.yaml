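# Demo scenario: three community stores over half a year of weekly sales.
# Purchasing pattern typical of remote-store surveillance: discretionary
# foods well above the upper-limit target, fruit and vegetables below their
# targets. 12.3% of discretionary energy goes to an unsubgrouped item, so
# the 13 named subgroups cover 87.7% of discretionary energy.
n_stores: 3
n_weeks: 26
target_indicators:
  fruit: 1.0
  vegetables: 2.0
  breads_cereals: 4.5
  meat_fish_eggs: 2.0
  dairy: 1.0
  unhealthy_foods: 6.0
noise: 0.15
unsubgrouped_share: 0.123
seed: 2024
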