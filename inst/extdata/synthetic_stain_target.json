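{"mean":[76.9783517971423,22.4076209126818,-5.06160277022701],"std":[6.5745847061959,3.8630488318475,5.85765613261201],"provenance":"ecsanet synthetic reference (seed 733)","colorspace":"CIELAB-D65"}
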