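# synthetic toy calibration curve (whitespace dialect)
# cal BP   14C age   error   extra_column
  500     604.5    14.4   0.915
  480     581.4    14.9   0.937
  460     558.6    14.9   0.286
  440     536.2    14.3   0.830
  420     514.5    13.3   0.642
  400     493.6    12.4   0.519
  380     473.6    12.0   0.737
  360     454.5    12.2   0.135
  340     436.4    13.0   0.657
  320     419.0    14.0   0.705
  300     402.4    14.8   0.458
  280     386.3    15.0   0.719
  260     370.6    14.6   0.935
  240     354.9    13.7   0.255
  220     339.1    12.8   0.462
  200     323.0    12.1   0.940
  180     306.3    12.1   0.978
  160     288.8    12.6   0.117
  140     270.6    13.6   0.475
  120     251.4    14.5   0.560
  100     231.2    15.0   0.904
   80     210.2    14.8   0.139
   60     188.4    14.1   0.989
   40     166.0    13.1   0.947
   20     143.1    12.3   0.082
    0     120.0    12.0   0.514
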