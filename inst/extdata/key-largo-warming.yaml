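# Seasonally variable site under the +1/+1.5/+1 degC summer overlay.
# Unset keys fall back to the standard parameterization.
site: key_largo
scenario:
  warming: true
n_replicates: 5
seed: 7
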