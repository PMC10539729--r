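# synthetic two-pulse echo decay (no measured data)
# generated from V(t) = exp[-(t/2.14 us)^2.01] + N(0, 0.005), t = 2 tau
# columns: total evolution time t = 2 tau (us), echo amplitude
0.100000 0.997482
0.179747 0.989673
0.259494 0.981412
0.339241 0.983134
0.418987 0.961049
0.498734 0.948369
0.578481 0.923299
0.658228 0.905945
0.737975 0.886424
0.817722 0.859021
0.897468 0.836582
0.977215 0.816523
1.056962 0.773432
1.136709 0.755000
1.216456 0.725281
1.296203 0.697126
1.375949 0.666603
1.455696 0.636857
1.535443 0.597094
1.615190 0.561895
1.694937 0.529230
1.774684 0.499840
1.854430 0.477405
1.934177 0.443638
2.013924 0.423195
2.093671 0.393661
2.173418 0.359138
2.253165 0.325524
2.332911 0.306471
2.412658 0.283359
2.492405 0.257761
2.572152 0.229282
2.651899 0.221599
2.731646 0.192714
2.811392 0.175547
2.891139 0.159042
2.970886 0.145693
3.050633 0.134446
3.130380 0.115679
3.210127 0.111849
3.289873 0.095647
3.369620 0.074554
3.449367 0.075859
3.529114 0.058376
3.608861 0.058919
3.688608 0.048878
3.768354 0.043915
3.848101 0.035785
3.927848 0.032634
4.007595 0.024961
4.087342 0.028253
4.167089 0.022078
4.246835 0.023610
4.326582 0.006318
4.406329 0.008300
4.486076 0.020255
4.565823 -0.000648
4.645570 0.011729
4.725316 -0.001140
4.805063 0.001031
4.884810 0.001174
4.964557 0.004784
5.044304 0.001657
5.124051 -0.011720
5.203797 0.001953
5.283544 -0.002499
5.363291 0.004766
5.443038 -0.006492
5.522785 0.001109
5.602532 -0.005913
5.682278 0.002724
5.762025 -0.001684
5.841772 0.004745
5.921519 -0.002801
6.001266 -0.003367
6.081013 0.002577
6.160759 -0.014028
6.240506 0.001232
6.320253 0.007343
6.400000 -0.001139
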