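   10
ARF1              0  1.37924  1.40833   1.5457  1.17236   1.2414  1.31801  0.595597  1.57044  1.52356
ARF5        1.37924        0  0.822003  0.858434  0.600815  0.476433  0.659081   1.5092  0.784951  0.678865
ARF7        1.40833  0.822003        0  0.560224  0.299036  0.487661  0.498053  1.45838  0.812168  0.61001
ARF16        1.5457  0.858434  0.560224        0  0.392354  0.674398  0.468402  1.50444  0.712044  0.639868
IAA2        1.17236  0.600815  0.299036  0.392354        0  0.697676  0.76071  1.54054  0.397677  0.737375
IAA3         1.2414  0.476433  0.487661  0.674398  0.697676        0  0.715856  1.19773  0.806865  0.456194
IAA8        1.31801  0.659081  0.498053  0.468402  0.76071  0.715856        0  1.26019  0.592883  0.777054
IAA12       0.595597   1.5092  1.45838  1.50444  1.54054  1.19773  1.26019        0  1.06713  1.34724
IAA17       1.57044  0.784951  0.812168  0.712044  0.397677  0.806865  0.592883  1.06713        0  0.75839
IAA28       1.52356  0.678865  0.61001  0.639868  0.737375  0.456194  0.777054  1.34724  0.75839        0
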