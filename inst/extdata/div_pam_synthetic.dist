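   10
ARF1              0  0.77273  0.777721  0.769078  0.580855  0.682172  0.745774  0.272707  0.846611  0.761947
ARF5        0.77273        0  0.576798  0.373224  0.36377  0.228718  0.255691  0.783132  0.418348  0.323124
ARF7        0.777721  0.576798        0  0.184812  0.157432  0.130286  0.189785  0.880309  0.317849  0.285621
ARF16       0.769078  0.373224  0.184812        0  0.167333  0.250547  0.161421  0.685075  0.289272  0.343049
IAA2        0.580855  0.36377  0.157432  0.167333        0  0.415064  0.239116  0.69366  0.109813  0.371148
IAA3        0.682172  0.228718  0.130286  0.250547  0.415064        0  0.296692  0.623043  0.452393  0.206164
IAA8        0.745774  0.255691  0.189785  0.161421  0.239116  0.296692        0  0.531294  0.221168  0.503479
IAA12       0.272707  0.783132  0.880309  0.685075  0.69366  0.623043  0.531294        0  0.443143  0.598175
IAA17       0.846611  0.418348  0.317849  0.289272  0.109813  0.452393  0.221168  0.443143        0  0.462063
IAA28       0.761947  0.323124  0.285621  0.343049  0.371148  0.206164  0.503479  0.598175  0.462063        0
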