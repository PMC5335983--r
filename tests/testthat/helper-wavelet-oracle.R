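# Frozen reference 36-dim stats encodings of the standard test signal,
# computed with an independent DWT implementation (PyWavelets 1.9.0,
# symmetric mode). Signal: gaussian humps at 90 and 150 plus a slow
# sine, length 235, 8 levels.
refStatsSignal <- function() {
  t <- 0:234
  exp(-0.5 * ((t - 90) / 4)^2) - 0.4 * exp(-0.5 * ((t - 150) / 12)^2) +
    0.1 * sin(2 * pi * t / 77)
}
refStatsFeatures <- list(
  "bior6.8" = c(0.66108562415358, -0.509916798769843, 0.229426600373454, 0.0935361963734084,
    0.615036924058142, -0.173802915326422, 0.0441680921903382, 0.0311881331162542,
    0.14598981837787, -1.53820319772458, -0.108875515886162, 0.128796553120564,
    0.793215114154259, -2.07417650643886, -0.0988636224111891, 0.262985689477984,
    0.589161226553485, -1.99334879310862, -0.0845227662598157, 0.192369425770365,
    1.01796993809158, -0.171997435116609, 0.0282393446215086, 0.038851936462802,
    0.303706159302181, -0.311679272522779, 0.000153745085913435, 0.00521461160645346,
    0.0181676125038973, -0.0372822751269975, -6.38605909120716e-06, 3.47797493490465e-05,
    0.00142425107638681, -0.00136769931102223, -1.83835254759291e-11, 7.85422792371262e-08),
  "db14" = c(1.52676479122804, 0.032945150672943, 0.986312306070569, 0.0958501116248039,
    0.79383314754565, -0.654656996344552, -0.000211274635572961, 0.0443345455219642,
    1.00768346386184, -0.958661805548997, 0.00163780784257167, 0.106188499374245,
    1.74210959587576, -1.89637876184029, 9.18148875531188e-05, 0.413625436012627,
    0.893183920482817, -1.37446017490658, 0.000915990410491031, 0.158671590753201,
    0.868350915291927, -0.833672644989553, 0.0107707387882258, 0.0812393124123729,
    0.26997905089636, -0.283982347163583, -0.000166406296369696, 0.00416752872303633,
    0.0140466877649581, -0.0115147186078239, 2.44800134171412e-05, 9.18703894954246e-06,
    0.00140101727629998, -0.00161139091806954, -4.69689189261098e-17, 6.26562788493496e-08),
  "sym8" = c(0.47927890039201, -0.413438949204767, 0.147426732363748, 0.0703992265352438,
    0.582745333634367, -0.802120468575871, -0.00495429817271795, 0.0796184930602665,
    0.847431614802472, -1.47978895363124, -0.0517247312195443, 0.183912069477172,
    0.692796916958679, -2.17285880062542, -0.115002657637885, 0.315114554629863,
    0.551262070975019, -1.71902503445325, -0.0528001652783856, 0.17570445254959,
    0.944872806201198, -0.561774777961022, 0.0093449889163485, 0.045183787018302,
    0.324888698526247, -0.499825266782499, -0.00123576290414431, 0.0120117969803659,
    0.024474631114505, -0.0190756366295284, 4.1600550857426e-06, 2.55474432537756e-05,
    0.0016916810974505, -0.00177467203832083, -3.3915534009693e-13, 7.83715902354945e-08),
  "coif5" = c(1.09888974599399, -0.525799456182513, 0.5344918039016, 0.325074238638501,
    0.758636493812069, -0.766768401928501, 0.0024995054263426, 0.0521940829703376,
    1.51506527321345, -1.6721755870149, -0.000826370673380302, 0.207044702681868,
    2.02198451514496, -1.61640798132458, 0.00022844812512697, 0.376973512461851,
    1.11568824410409, -0.653551205608918, 0.0015627206424023, 0.114690547784041,
    0.368543807306105, -1.54338169869367, -0.0254527937355977, 0.0665724754866402,
    0.0906959929783285, -0.0768099624885641, 0.000742527863560216, 0.000471091953661804,
    0.0156196856773383, -0.0106811734864368, 4.47797537828965e-05, 1.26045666548464e-05,
    0.0013701362563124, -0.00157977956151076, -1.95201140172513e-14, 6.48693740140447e-08),
  "fk22" = c(0.986034650079539, 0.119434159805045, 0.762134396930497, 0.040079590161582,
    1.34124933722912, -0.386954821188884, -0.0175527633403493, 0.117923412558403,
    0.772725731262519, -0.513886386245008, -0.00525283596725694, 0.0624079239919932,
    0.951092700560499, -1.16252525393121, -0.00225821008325547, 0.141063017931056,
    1.00179721426075, -1.38398587372048, 0.004107836647903, 0.13955531618019,
    0.780465174321143, -1.12082936687803, -0.00872621251657435, 0.129369290477193,
    0.531673871632446, -1.11601869181751, 0.0168471408345677, 0.0788824057680498,
    0.469990395549922, -0.771651393805171, 0.0065959994279198, 0.037736090256684,
    0.411475778175368, -0.549946532821874, 0.00216359693841697, 0.013791267182279),
  "rbio6.8" = c(0.644756315160017, -0.451147388948316, 0.213986481568563, 0.099464075163838,
    0.543044119631512, -0.245205988939244, 0.0417949840360015, 0.0238681673134804,
    0.125515884436903, -1.41397142474734, -0.0894523193772492, 0.111542591983453,
    0.965218866354975, -2.015347504941, -0.0866443835611438, 0.264355345431409,
    0.571657831748625, -1.87536450057148, -0.0645327490174979, 0.187184105247359,
    0.9570413832069, -0.224336787559011, 0.0202660203299705, 0.0344874159017398,
    0.345176984351642, -0.37286269297534, 0.000287102425737352, 0.00779069558673125,
    0.0247711116574761, -0.0440290376996566, -1.1846465692924e-05, 5.18080072003921e-05,
    0.00171363740006102, -0.00164559254034387, -2.41146272461192e-13, 1.01760766310516e-07)
)
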