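# Arsenic fish-ingestion non-cancer risk: packaged case-study configuration.
# The model itself (evaluator + Table-of-parameters) is built in, so this
# file only pins the propagation and summary settings.
model: arsenic
n_mc: 5000
seed: 20170131
alpha_steps: 10
fractiles:
- 0.95
- 0.85
range_percentiles:
- 0.005
- 0.995
quantile_mode: empirical
variance_divisor: population
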