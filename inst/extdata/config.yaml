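# Default campaign configuration for the bowel / abdominal-wall task set.
# MV is an absolute per-pixel vote-count threshold: a consensus pixel needs
# at least `mv` of the (at least) `n_min` qualified annotations.
structures:
  bowel: {n_min: 5, mv: 4}
  abdominal_wall: {n_min: 5, mv: 2}
# Qualification gates. The production platform's cutoffs are not public;
# these defaults are conservative and meant to be overridden.
ts_min: 0.5
rs_min: 0.5
n_training_gold: 10
# Running-score monitoring: one hidden gold test per ~20 ordinary tasks,
# scored over the 10 most recent tests.
rs_cadence: 20
rs_window: 10
# QA routing: frames with difficulty index above rt are eligible for expert
# review and sampled at qa_sampling_rate.
rt: 0.4
qa_sampling_rate: 0.1
# Expert-time accounting.
expert_seconds_per_frame: 120.3
experts_available: 4
expert_hours_per_day: 1
seed: 1
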