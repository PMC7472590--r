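V2
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100.055
100.219
100.489
100.865
101.34
101.91
102.569
103.309
104.122
105
105.933
106.91
107.921
108.955
110
111.045
112.079
113.09
114.067
115
115.878
116.691
117.431
118.09
118.66
119.135
119.511
119.781
119.945
120
119.945
119.781
119.511
119.135
118.66
118.09
117.431
116.691
115.878
115
114.067
113.09
112.079
111.045
110
108.955
107.921
106.91
105.933
105
104.122
103.309
102.569
101.91
101.34
100.865
100.489
100.219
100.055
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100.67
102.67
105.969
110.514
116.234
123.038
130.819
139.455
148.809
158.734
169.073
179.663
190.337
200.927
211.266
221.191
230.545
239.181
246.962
253.766
259.486
264.031
267.33
269.33
270
269.33
267.33
264.031
259.486
253.766
246.962
239.181
230.545
220.765
209.592
197.266
184.087
170.398
156.573
142.998
130.059
118.116
107.494
98.464
91.234
85.94
82.644
81.332
81.92
84.265
88.642
95.129
103.01
111.339
119.066
125.181
128.858
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130
130.035
130.14
130.314
130.557
130.869
131.248
131.694
132.205
132.779
133.416
134.114
134.87
135.683
136.55
137.469
138.437
139.452
140.511
141.612
142.75
143.841
144.8
145.627
146.323
146.89
147.334
147.658
147.871
147.982
148
147.936
147.801
147.608
147.37
147.1
146.812
146.52
146.237
145.976
145.75
145.572
145.452
145.4
145.428
145.541
145.747
146.051
146.458
146.968
147.584
148.221
148.795
149.306
149.752
150.131
150.443
150.686
150.86
150.965
151
150.965
150.86
150.686
150.443
150.131
149.752
149.306
148.795
148.221
147.584
146.886
146.13
145.317
144.45
143.531
142.563
141.548
140.489
139.388
138.25
137.077
135.872
134.638
133.38
132.1
130.802
129.489
128.165
126.835
125.5
124.165
122.835
121.511
120.198
118.9
117.62
116.362
115.128
113.923
112.75
111.612
110.511
109.452
108.437
107.469
106.55
105.683
104.87
104.114
103.416
102.779
102.205
101.694
101.248
100.869
100.557
100.314
100.14
100.035
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
100
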