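# Decomposition filter banks for the supported wavelet families.
# Orthogonal families (db14, sym8, coif5, fk22) and the biorthogonal
# spline pair bior6.8/rbio6.8. Stored in decomposition (analysis)
# orientation; fk22 is a Fejer-Korovkin-type filter obtained by
# spectral factorization of a halfband polynomial built from the
# order-23 Fejer-Korovkin kernel.
.waveletFilters <- list(
  "bior6.8" = list(
    loD = c(0, 0.0019088317364812906, -0.0019142861290887667, -0.016990639867602342, 0.01193456527972926, 0.04973290349094079, -0.077263173167204144, -0.09405920349573646, 0.42079628460982682, 0.82592299745840225, 0.42079628460982682, -0.09405920349573646, -0.077263173167204144, 0.04973290349094079, 0.01193456527972926, -0.016990639867602342, -0.0019142861290887667, 0.0019088317364812906),
    hiD = c(-0, 0, -0, 0.014426282505624435, -0.014467504896790148, -0.078722001062628819, 0.040367979030339923, 0.41784910915027457, -0.75890772945365415, 0.41784910915027457, 0.040367979030339923, -0.078722001062628819, -0.014467504896790148, 0.014426282505624435, -0, 0, -0, 0)
  ),
  "db14" = list(
    loD = c(-1.7871399683113592e-07, 1.7249946753678127e-06, -4.3897049017813942e-06, -1.0337209184570774e-05, 6.8755042526975093e-05, -4.1777245770372596e-05, -0.0003868319473129545, 0.00070802115423552786, 0.0010616910856067619, -0.0038496388680221874, -0.00074621898926838497, 0.012789493266333409, -0.0056150495303569593, -0.030185351540390634, 0.026981408307912916, 0.055237126259216042, -0.071548955504046136, -0.086748411568169689, 0.1399890165844607, 0.1383952138648066, -0.21803352999327605, -0.27168855227874805, 0.21867068775890652, 0.63118784910485681, 0.55430561794089384, 0.25485026779262138, 0.062364758849398898, 0.0064611534600879476),
    hiD = c(-0.0064611534600879476, 0.062364758849398898, -0.25485026779262138, 0.55430561794089384, -0.63118784910485681, 0.21867068775890652, 0.27168855227874805, -0.21803352999327605, -0.1383952138648066, 0.1399890165844607, 0.086748411568169689, -0.071548955504046136, -0.055237126259216042, 0.026981408307912916, 0.030185351540390634, -0.0056150495303569593, -0.012789493266333409, -0.00074621898926838497, 0.0038496388680221874, 0.0010616910856067619, -0.00070802115423552786, -0.0003868319473129545, 4.1777245770372596e-05, 6.8755042526975093e-05, 1.0337209184570774e-05, -4.3897049017813942e-06, -1.7249946753678127e-06, -1.7871399683113592e-07)
  ),
  "sym8" = list(
    loD = c(-0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981, 0.0076074873249176054, -0.14329423835080971, -0.061273359067658524, 0.48135965125837221, 0.77718575170052351, 0.3644418948353314, -0.051945838107709037, -0.027219029917056003, 0.049137179673607506, 0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668, 0.0018899503327594609),
    hiD = c(-0.0018899503327594609, -0.0003029205147213668, 0.014952258337048231, 0.0038087520138906151, -0.049137179673607506, -0.027219029917056003, 0.051945838107709037, 0.3644418948353314, -0.77718575170052351, 0.48135965125837221, 0.061273359067658524, -0.14329423835080971, -0.0076074873249176054, 0.031695087811492981, 0.00054213233179114812, -0.0033824159510061256)
  ),
  "coif5" = list(
    loD = c(-9.6040101127678941e-08, -1.6237995172048338e-07, 2.0612203985788783e-06, 3.7007277113394796e-06, -2.1270221672515614e-05, -4.1219861924265501e-05, 0.00014035632812373243, 0.00030185794166824478, -0.00063755892612588115, -0.0016616273039298788, 0.0024315754425382886, 0.0067615202206204169, -0.0091595073386761625, -0.019758391600965465, 0.032674799467057355, 0.041287530472117834, -0.10556315130733723, -0.06203775157498196, 0.43798230665916338, 0.77429362286032744, 0.42157126673075435, -0.052046670253554764, -0.091921588060086087, 0.028169744270532353, 0.023408322118927783, -0.010131584846900276, -0.0041593126275786402, 0.0021782943778456947, 0.00035857774116175768, -0.000212081862067494),
    hiD = c(0.000212081862067494, 0.00035857774116175768, -0.0021782943778456947, -0.0041593126275786402, 0.010131584846900276, 0.023408322118927783, -0.028169744270532353, -0.091921588060086087, 0.052046670253554764, 0.42157126673075435, -0.77429362286032744, 0.43798230665916338, 0.06203775157498196, -0.10556315130733723, -0.041287530472117834, 0.032674799467057355, 0.019758391600965465, -0.0091595073386761625, -0.0067615202206204169, 0.0024315754425382886, 0.0016616273039298788, -0.00063755892612588115, -0.00030185794166824478, 0.00014035632812373243, 4.1219861924265501e-05, -2.1270221672515614e-05, -3.7007277113394796e-06, 2.0612203985788783e-06, 1.6237995172048338e-07, -9.6040101127678941e-08)
  ),
  "fk22" = list(
    loD = c(0.00018267755780244666, -3.3572811590626359e-05, 0.0018078659346823752, -0.00036396888223166532, 0.0062572166417903139, -0.0014922456494108512, 0.014683684000042076, -0.0040902147352034216, 0.027840497935915743, -0.0088972411176483548, 0.045942855519164404, -0.016594381446959627, 0.068578341503363588, -0.02767242222828523, 0.094678410195928764, -0.042311455393787237, 0.1225581228092562, -0.060288605457009502, 0.1500251149718923, -0.080927532499421917, 0.17455199411670941, 0.94977842140809599),
    hiD = c(-0.94977842140809599, 0.17455199411670941, 0.080927532499421917, 0.1500251149718923, 0.060288605457009502, 0.1225581228092562, 0.042311455393787237, 0.094678410195928764, 0.02767242222828523, 0.068578341503363588, 0.016594381446959627, 0.045942855519164404, 0.0088972411176483548, 0.027840497935915743, 0.0040902147352034216, 0.014683684000042076, 0.0014922456494108512, 0.0062572166417903139, 0.00036396888223166532, 0.0018078659346823752, 3.3572811590626359e-05, 0.00018267755780244666)
  ),
  "rbio6.8" = list(
    loD = c(0, 0, 0, 0, 0.014426282505624435, 0.014467504896790148, -0.078722001062628819, -0.040367979030339923, 0.41784910915027457, 0.75890772945365415, 0.41784910915027457, -0.040367979030339923, -0.078722001062628819, 0.014467504896790148, 0.014426282505624435, 0, 0, 0),
    hiD = c(-0.0019088317364812906, -0.0019142861290887667, 0.016990639867602342, 0.01193456527972926, -0.04973290349094079, -0.077263173167204144, 0.09405920349573646, 0.42079628460982682, -0.82592299745840225, 0.42079628460982682, 0.09405920349573646, -0.077263173167204144, -0.04973290349094079, 0.01193456527972926, 0.016990639867602342, -0.0019142861290887667, -0.0019088317364812906, 0)
  )
)
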