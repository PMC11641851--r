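# Filter tap tables for the ten supported mother wavelets.
# Double-precision values from the standard published definitions.
.wavelet_filters <- list(
  `db1` = list(name = "db1", orthogonal = TRUE,
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476)),
  `db2` = list(name = "db2", orthogonal = TRUE,
    dec_lo = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079, 0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.8365163037378079, -0.2241438680420134, -0.12940952255126037),
    rec_lo = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134, -0.12940952255126037),
    rec_hi = c(-0.12940952255126037, -0.2241438680420134, 0.8365163037378079, -0.48296291314453416)),
  `db4` = list(name = "db4", orthogonal = TRUE,
    dec_lo = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764, -0.18703481171909309, -0.027983769416859854, 0.6308807679298589, 0.7148465705529157, 0.2303778133088965),
    dec_hi = c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589, -0.027983769416859854, 0.18703481171909309, 0.030841381835560764, -0.0328830116668852, -0.010597401785069032),
    rec_lo = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589, -0.027983769416859854, -0.18703481171909309, 0.030841381835560764, 0.0328830116668852, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.0328830116668852, 0.030841381835560764, 0.18703481171909309, -0.027983769416859854, -0.6308807679298589, 0.7148465705529157, -0.2303778133088965)),
  `coif1` = list(name = "coif1", orthogonal = TRUE,
    dec_lo = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578, 0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    dec_hi = c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004, 0.3848648468648578, 0.07273261951252645, -0.015655728135791993),
    rec_lo = c(-0.07273261951252645, 0.3378976624574818, 0.8525720202116004, 0.3848648468648578, -0.07273261951252645, -0.015655728135791993),
    rec_hi = c(-0.015655728135791993, 0.07273261951252645, 0.3848648468648578, -0.8525720202116004, 0.3378976624574818, 0.07273261951252645)),
  `coif5` = list(name = "coif5", orthogonal = TRUE,
    dec_lo = c(-9.604010112767894e-08, -1.6237995172048338e-07, 2.0612203985788783e-06, 3.7007277113394796e-06, -2.1270221672515614e-05, -4.12198619242655e-05, 0.00014035632812373243, 0.0003018579416682448, -0.0006375589261258812, -0.0016616273039298788, 0.0024315754425382886, 0.006761520220620417, -0.009159507338676163, -0.019758391600965465, 0.032674799467057355, 0.041287530472117834, -0.10556315130733723, -0.06203775157498196, 0.4379823066591634, 0.7742936228603274, 0.42157126673075435, -0.052046670253554764, -0.09192158806008609, 0.028169744270532353, 0.023408322118927783, -0.010131584846900276, -0.00415931262757864, 0.0021782943778456947, 0.0003585777411617577, -0.000212081862067494),
    dec_hi = c(0.000212081862067494, 0.0003585777411617577, -0.0021782943778456947, -0.00415931262757864, 0.010131584846900276, 0.023408322118927783, -0.028169744270532353, -0.09192158806008609, 0.052046670253554764, 0.42157126673075435, -0.7742936228603274, 0.4379823066591634, 0.06203775157498196, -0.10556315130733723, -0.041287530472117834, 0.032674799467057355, 0.019758391600965465, -0.009159507338676163, -0.006761520220620417, 0.0024315754425382886, 0.0016616273039298788, -0.0006375589261258812, -0.0003018579416682448, 0.00014035632812373243, 4.12198619242655e-05, -2.1270221672515614e-05, -3.7007277113394796e-06, 2.0612203985788783e-06, 1.6237995172048338e-07, -9.604010112767894e-08),
    rec_lo = c(-0.000212081862067494, 0.0003585777411617577, 0.0021782943778456947, -0.00415931262757864, -0.010131584846900276, 0.023408322118927783, 0.028169744270532353, -0.09192158806008609, -0.052046670253554764, 0.42157126673075435, 0.7742936228603274, 0.4379823066591634, -0.06203775157498196, -0.10556315130733723, 0.041287530472117834, 0.032674799467057355, -0.019758391600965465, -0.009159507338676163, 0.006761520220620417, 0.0024315754425382886, -0.0016616273039298788, -0.0006375589261258812, 0.0003018579416682448, 0.00014035632812373243, -4.12198619242655e-05, -2.1270221672515614e-05, 3.7007277113394796e-06, 2.0612203985788783e-06, -1.6237995172048338e-07, -9.604010112767894e-08),
    rec_hi = c(-9.604010112767894e-08, 1.6237995172048338e-07, 2.0612203985788783e-06, -3.7007277113394796e-06, -2.1270221672515614e-05, 4.12198619242655e-05, 0.00014035632812373243, -0.0003018579416682448, -0.0006375589261258812, 0.0016616273039298788, 0.0024315754425382886, -0.006761520220620417, -0.009159507338676163, 0.019758391600965465, 0.032674799467057355, -0.041287530472117834, -0.10556315130733723, 0.06203775157498196, 0.4379823066591634, -0.7742936228603274, 0.42157126673075435, 0.052046670253554764, -0.09192158806008609, -0.028169744270532353, 0.023408322118927783, 0.010131584846900276, -0.00415931262757864, -0.0021782943778456947, 0.0003585777411617577, 0.000212081862067494)),
  `bior22` = list(name = "bior22", orthogonal = FALSE,
    dec_lo = c(0.0, -0.1767766952966369, 0.3535533905932738, 1.0606601717798212, 0.3535533905932738, -0.1767766952966369),
    dec_hi = c(-0.0, 0.3535533905932738, -0.7071067811865476, 0.3535533905932738, -0.0, 0.0),
    rec_lo = c(0.0, 0.3535533905932738, 0.7071067811865476, 0.3535533905932738, 0.0, 0.0),
    rec_hi = c(0.0, 0.1767766952966369, 0.3535533905932738, -1.0606601717798212, 0.3535533905932738, 0.1767766952966369)),
  `bior33` = list(name = "bior33", orthogonal = FALSE,
    dec_lo = c(0.06629126073623882, -0.1988737822087165, -0.15467960838455727, 0.9943689110435825, 0.9943689110435825, -0.15467960838455727, -0.1988737822087165, 0.06629126073623882),
    dec_hi = c(-0.0, 0.0, -0.1767766952966369, 0.5303300858899106, -0.5303300858899106, 0.1767766952966369, -0.0, 0.0),
    rec_lo = c(0.0, 0.0, 0.1767766952966369, 0.5303300858899106, 0.5303300858899106, 0.1767766952966369, 0.0, 0.0),
    rec_hi = c(0.06629126073623882, 0.1988737822087165, -0.15467960838455727, -0.9943689110435825, 0.9943689110435825, 0.15467960838455727, -0.1988737822087165, -0.06629126073623882)),
  `sym2` = list(name = "sym2", orthogonal = TRUE,
    dec_lo = c(-0.12940952255092145, 0.22414386804185735, 0.836516303737469, 0.48296291314469025),
    dec_hi = c(-0.48296291314469025, 0.836516303737469, -0.22414386804185735, -0.12940952255092145),
    rec_lo = c(0.48296291314469025, 0.836516303737469, 0.22414386804185735, -0.12940952255092145),
    rec_hi = c(-0.12940952255092145, -0.22414386804185735, 0.836516303737469, -0.48296291314469025)),
  `sym3` = list(name = "sym3", orthogonal = TRUE,
    dec_lo = c(0.035226291882100656, -0.08544127388224149, -0.13501102001039084, 0.4598775021193313, 0.8068915093133388, 0.3326705529509569),
    dec_hi = c(-0.3326705529509569, 0.8068915093133388, -0.4598775021193313, -0.13501102001039084, 0.08544127388224149, 0.035226291882100656),
    rec_lo = c(0.3326705529509569, 0.8068915093133388, 0.4598775021193313, -0.13501102001039084, -0.08544127388224149, 0.035226291882100656),
    rec_hi = c(0.035226291882100656, 0.08544127388224149, -0.13501102001039084, -0.4598775021193313, 0.8068915093133388, -0.3326705529509569)),
  `sym5` = list(name = "sym5", orthogonal = TRUE,
    dec_lo = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094, 0.1993975339773936, 0.7234076904024206, 0.6339789634582119, 0.01660210576452232, -0.17532808990845047, -0.021101834024758855, 0.019538882735286728),
    dec_hi = c(-0.019538882735286728, -0.021101834024758855, 0.17532808990845047, 0.01660210576452232, -0.6339789634582119, 0.7234076904024206, -0.1993975339773936, -0.039134249302383094, -0.029519490925774643, 0.027333068345077982),
    rec_lo = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047, 0.01660210576452232, 0.6339789634582119, 0.7234076904024206, 0.1993975339773936, -0.039134249302383094, 0.029519490925774643, 0.027333068345077982),
    rec_hi = c(0.027333068345077982, -0.029519490925774643, -0.039134249302383094, -0.1993975339773936, 0.7234076904024206, -0.6339789634582119, 0.01660210576452232, 0.17532808990845047, -0.021101834024758855, -0.019538882735286728))
)
# db1: taps 2 orth True sum_lo 1.414213562373 sum_hi 0.000e+00
# db2: taps 4 orth True sum_lo 1.414213562373 sum_hi 2.776e-17
# db4: taps 8 orth True sum_lo 1.414213562373 sum_hi 1.908e-17
# coif1: taps 6 orth True sum_lo 1.414213562373 sum_hi 1.284e-16
# coif5: taps 30 orth True sum_lo 1.414213562373 sum_hi 6.553e-17
# bior2.2: taps 6 orth False sum_lo 1.414213562373 sum_hi 0.000e+00
# bior3.3: taps 8 orth False sum_lo 1.414213562373 sum_hi 2.776e-17
# sym2: taps 4 orth True sum_lo 1.414213562373 sum_hi -5.551e-17
# sym3: taps 6 orth True sum_lo 1.414213562373 sum_hi -2.998e-12
# sym5: taps 10 orth True sum_lo 1.414213562373 sum_hi -3.337e-12
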