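pair	anterior_rois	posterior_rois	posterior_to_rois
D1&D2	35.5	58.1	65.2
D2&D3	36.9	69.8	69.7
D3&D4	51.4	80.3	74.5
D4&D5	47.4	75.1	72.9
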