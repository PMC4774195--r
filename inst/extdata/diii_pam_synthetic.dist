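   10
ARF1              0  0.606512  0.630614  0.776627  0.591502  0.559226  0.572238  0.32289  0.723825  0.761615
ARF5        0.606512        0  0.245205  0.48521  0.237045  0.247715  0.403391  0.726064  0.366603  0.355741
ARF7        0.630614  0.245205        0  0.375412  0.141604  0.357375  0.308268  0.578068  0.494319  0.32439
ARF16       0.776627  0.48521  0.375412        0  0.225021  0.42385  0.306981  0.819363  0.422772  0.296818
IAA2        0.591502  0.237045  0.141604  0.225021        0  0.282612  0.521594  0.846879  0.287864  0.366227
IAA3        0.559226  0.247715  0.357375  0.42385  0.282612        0  0.419165  0.57469  0.354472  0.25003
IAA8        0.572238  0.403391  0.308268  0.306981  0.521594  0.419165        0  0.728897  0.371715  0.273574
IAA12       0.32289  0.726064  0.578068  0.819363  0.846879  0.57469  0.728897        0  0.623982  0.749065
IAA17       0.723825  0.366603  0.494319  0.422772  0.287864  0.354472  0.371715  0.623982        0  0.296327
IAA28       0.761615  0.355741  0.32439  0.296818  0.366227  0.25003  0.273574  0.749065  0.296327        0
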