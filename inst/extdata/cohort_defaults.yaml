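# Default synthetic post-stroke cohort configuration.
#
# Group-conditional means/SDs, binary-index probabilities and group sizes are
# the published descriptive statistics of a 274-patient rehabilitation-ward
# cohort grouped as control / depression / apathy / anxiety (sizes 80/40/80/40).
# The exact 36-index feature list used in that study is not published; this
# schema is a reconstruction from the printed cohort table (35 continuous
# indices including JPSS, plus 4 binary flags). All values are SYNTHETIC
# generator parameters, not patient data.
#
# Group order everywhere: [control, depression, apathy, anxiety]
groups:
  names: [control, depression, apathy, anxiety]
  sizes: [80, 40, 80, 40]
thresholds:
  hads_cutoff: 9      # disorder present when score > cutoff (strict)
  apathy_cutoff: 16
factors:
  stress_loading: 0.5   # shared latent "perceived stress" factor
  speed_loading: 0.4    # shared latent "processing speed" factor (time indices)
  mode: mix             # "mix": variance-preserving (index SDs stay as printed);
                        # "additive": loading adds shared variance on top
continuous:
  motor_fim_admission:            {mean: [62.8, 62.0, 63.7, 66.9], sd: [20.8, 22.5, 20.6, 22.0], bounds: [13, 91]}
  cognitive_fim_admission:        {mean: [29.2, 25.3, 26.3, 26.4], sd: [5.5, 7.2, 7.3, 8.4], bounds: [5, 35]}
  motor_fim_discharge:            {mean: [82.5, 80.2, 81.0, 81.7], sd: [10.1, 10.1, 9.8, 8.5], bounds: [13, 91]}
  cognitive_fim_discharge:        {mean: [32.2, 29.5, 29.9, 30.4], sd: [3.7, 5.0, 4.7, 5.3], bounds: [5, 35]}
  motor_fim_improvement_rate:     {mean: [3.3, 1.9, 2.2, 1.8], sd: [3.5, 1.8, 2.2, 2.7], bounds: [-10, 20]}
  cognitive_fim_improvement_rate: {mean: [0.6, 0.4, 0.4, 0.4], sd: [1.4, 0.5, 0.5, 0.7], bounds: [-5, 10]}
  brs_total_admission:            {mean: [15.3, 14.3, 14.8, 14.7], sd: [3.9, 4.4, 4.3, 4.4], bounds: [3, 18]}
  brs_total_discharge:            {mean: [16.4, 15.9, 16.3, 16.2], sd: [3.2, 3.0, 2.8, 2.8], bounds: [3, 18]}
  mmse:                           {mean: [27.5, 26.1, 26.2, 26.9], sd: [2.4, 3.9, 4.0, 4.0], bounds: [0, 30]}
  bit_conventional:               {mean: [141.4, 137.9, 138.2, 140.0], sd: [8.0, 10.3, 11.0, 7.3], bounds: [0, 146]}
  bit_behavioural:                {mean: [78.5, 76.5, 75.7, 77.7], sd: [6.9, 6.1, 11.4, 6.0], bounds: [0, 81]}
  digit_span_forward:             {mean: [5.5, 5.3, 5.4, 5.6], sd: [1.1, 1.3, 1.0, 1.4], bounds: [0, 14]}
  digit_span_backward:            {mean: [4.1, 3.8, 3.9, 4.3], sd: [1.0, 1.3, 1.2, 1.3], bounds: [0, 14]}
  tapping_span_forward:           {mean: [5.7, 5.5, 5.4, 5.7], sd: [1.4, 1.2, 1.3, 1.2], bounds: [0, 14]}
  tapping_span_backward:          {mean: [4.9, 4.8, 4.4, 4.9], sd: [1.4, 1.3, 1.2, 1.4], bounds: [0, 14]}
  cancellation_kana_accuracy:     {mean: [93.8, 90.8, 93.1, 93.8], sd: [9.9, 11.4, 8.4, 7.2], bounds: [0, 100]}
  cancellation_triangle_accuracy: {mean: [97.1, 96.8, 97.1, 98.1], sd: [6.9, 5.9, 4.2, 3.4], bounds: [0, 100]}
  cancellation_star_accuracy:     {mean: [97.7, 97.3, 97.5, 98.7], sd: [9.7, 7.2, 5.9, 3.4], bounds: [0, 100]}
  cancellation_three_accuracy:    {mean: [98.0, 97.4, 97.6, 97.8], sd: [9.1, 6.0, 6.1, 5.0], bounds: [0, 100]}
  cancellation_kana_time:         {mean: [136.8, 183.1, 175.2, 169.0], sd: [42.4, 126.5, 100.5, 59.5], bounds: [10, 900], factor: speed}
  cancellation_triangle_time:     {mean: [62.6, 78.0, 77.2, 78.2], sd: [22.9, 47.9, 38.3, 32.3], bounds: [5, 600], factor: speed}
  cancellation_star_time:         {mean: [74.9, 102.1, 102.2, 91.2], sd: [25.5, 94.2, 86.9, 33.8], bounds: [5, 900], factor: speed}
  cancellation_three_time:        {mean: [113.0, 140.7, 137.9, 132.1], sd: [31.8, 60.4, 64.1, 41.6], bounds: [10, 900], factor: speed}
  sdmt_wrong_answers:             {mean: [0.8, 0.9, 1.0, 1.1], sd: [1.6, 1.0, 1.3, 1.4], bounds: [0, 110]}
  sdmt_achievement_rate:          {mean: [35.9, 28.2, 28.2, 29.4], sd: [11.7, 11.0, 12.0, 11.5], bounds: [0, 100]}
  memory_updating_3_accuracy:     {mean: [64.7, 62.8, 59.1, 60.1], sd: [22.4, 23.1, 24.6, 25.5], bounds: [0, 100]}
  pasat_2s_accuracy:              {mean: [47.2, 34.4, 37.2, 38.1], sd: [22.5, 19.6, 20.2, 20.2], bounds: [0, 100]}
  stroop_accuracy:                {mean: [96.0, 90.7, 93.7, 93.1], sd: [12.5, 18.9, 12.6, 16.3], bounds: [0, 100]}
  stroop_time:                    {mean: [107.3, 138.3, 142.1, 118.6], sd: [43.4, 91.8, 81.9, 53.2], bounds: [10, 900], factor: speed}
  cpt_srt_time:                   {mean: [363.7, 410.5, 401.3, 386.1], sd: [99.9, 108.1, 91.4, 91.8], bounds: [100, 2000], factor: speed}
  cpt_x_time:                     {mean: [534.2, 563.2, 574.3, 555.2], sd: [87.6, 82.2, 103.1, 105.6], bounds: [100, 2000], factor: speed}
  cpt_ax_time:                    {mean: [547.3, 581.1, 589.5, 563.2], sd: [104.2, 133.0, 118.7, 119.4], bounds: [100, 2000], factor: speed}
  tmt_a_time:                     {mean: [55.0, 76.9, 70.9, 72.6], sd: [29.4, 51.6, 44.1, 45.7], bounds: [5, 900], factor: speed}
  tmt_b_time:                     {mean: [108.2, 146.7, 134.5, 146.1], sd: [38.6, 57.9, 58.9, 57.9], bounds: [10, 900], factor: speed}
  rbmt_profile:                   {mean: [20.1, 17.8, 17.0, 17.7], sd: [3.5, 4.5, 4.7, 4.6], bounds: [0, 24]}
  jpss:                           {mean: [16.1, 25.7, 23.3, 25.2], sd: [6.5, 6.6, 6.4, 6.9], bounds: [0, 56], factor: stress}
binary:
  ataxia:      {prob: [0.050, 0.050, 0.113, 0.075]}
  aphasia:     {prob: [0.100, 0.200, 0.138, 0.150]}
  tmt_a_fail:  {prob: [0.038, 0.025, 0.063, 0.025]}
  tmt_b_fail:  {prob: [0.275, 0.425, 0.450, 0.375]}
# Psychological instruments that define the disorder labels (not features)
scores:
  hads_depression: {mean: [2.3, 11.1, 6.7, 7.4], sd: [1.7, 2.4, 3.4, 3.8], bounds: [0, 21], factor: stress}
  hads_anxiety:    {mean: [2.9, 7.9, 6.4, 10.7], sd: [2.0, 4.1, 3.3, 2.3], bounds: [0, 21], factor: stress}
  apathy_score:    {mean: [5.1, 16.7, 20.2, 14.5], sd: [2.8, 6.9, 4.2, 6.5], bounds: [0, 42], factor: stress}
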