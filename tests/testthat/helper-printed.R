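# Enrichment rows as printed by the published T2D meta-analysis workflow
# this package re-implements: overlap k, query size n, term size m, the
# printed raw p, odds ratio, and combined score. The printed p-values
# themselves are not reproducible (the external service's effective
# background is unknown); the odds-ratio and combined-score arithmetic is.
printed_enrichment_rows <- function() {
  rows <- rbind(
    # GO biological processes, highly perturbed set (n = 79)
    c(3, 79, 48, 9.03e-4, 17.43509, 122.2228),
    c(2, 79, 20, 0.002795, 28.72006, 168.8714),
    c(2, 79, 28, 0.005448, 19.87512, 103.5986),
    c(3, 79, 115, 0.010668, 6.981555, 31.69995),
    c(3, 79, 118, 0.011436, 6.798398, 30.39569),
    c(2, 79, 43, 0.012527, 12.59424, 55.1606),
    c(2, 79, 44, 0.013091, 12.29375, 53.30386),
    c(2, 79, 45, 0.013665, 12.00725, 51.54622),
    c(2, 79, 47, 0.014845, 11.47244, 48.2997),
    c(2, 79, 50, 0.016695, 10.75379, 44.01114),
    # KEGG pathways, highly perturbed set (n = 79)
    c(6, 79, 201, 0.000144, 8.31444, 73.51986),
    c(4, 79, 77, 0.000245, 14.50082, 120.5547),
    c(3, 79, 53, 0.001205, 15.68763, 105.436),
    c(2, 79, 26, 0.004708, 21.53355, 115.3862),
    c(2, 79, 31, 0.006651, 17.81639, 89.31323),
    c(2, 79, 38, 0.009878, 14.34704, 66.24726),
    c(2, 79, 41, 0.011434, 13.24142, 59.20461),
    c(2, 79, 48, 0.015452, 11.22247, 46.79817),
    c(3, 79, 145, 0.019771, 5.498242, 21.5726),
    # COVID-19 / HMDB rows, highly perturbed set (n = 79)
    c(9, 79, 500, 0.000155, 5.08787, 44.64083),
    c(5, 79, 246, 0.002908, 5.51755, 32.22428),
    c(6, 79, 366, 0.003262, 4.46598, 25.56907),
    c(7, 79, 500, 0.003599, 3.8313, 21.55896),
    c(4, 79, 82, 0.000312, 13.56786, 109.52001),
    c(4, 79, 193, 0.007193, 5.56811, 27.4768),
    c(6, 79, 463, 0.009991, 3.50061, 16.12387),
    c(1, 79, 11, 0.042612, 25.52692, 80.55315),
    # GO / KEGG rows, hub set (n = 28)
    c(5, 28, 479, 0.000481, 8.94239, 68.31934),
    c(5, 28, 483, 0.000499, 8.86574, 67.39777),
    c(5, 28, 487, 0.000518, 8.79036, 66.49468),
    c(2, 28, 47, 0.001965, 34.06324, 212.28967),
    c(2, 28, 62, 0.003393, 25.5282, 145.15226),
    c(2, 28, 63, 0.003501, 25.10844, 141.97721),
    c(2, 28, 65, 0.003722, 24.30891, 135.96666),
    c(2, 28, 73, 0.004671, 21.56121, 115.70462),
    c(2, 28, 86, 0.006424, 18.21245, 91.9304),
    c(1, 28, 21, 0.029006, 36.94814, 130.80559),
    c(1, 28, 26, 0.035792, 29.55111, 98.40622),
    c(1, 28, 27, 0.037143, 28.4131, 93.5634),
    # COVID-19 / HMDB rows, hub set (n = 28)
    c(5, 28, 246, 0.000021, 17.79812, 191.63596),
    c(4, 28, 500, 0.004909, 6.54435, 34.79441),
    c(3, 28, 264, 0.005837, 9.06253, 46.61365),
    c(2, 28, 92, 0.007319, 16.99316, 83.55855),
    c(4, 28, 82, 4.99e-6, 42.50854, 518.98916),
    c(1, 28, 13, 0.018053, 61.60493, 247.30909),
    c(1, 28, 14, 0.019428, 56.86324, 224.09815),
    c(1, 28, 15, 0.020802, 52.79894, 204.47351),
    c(1, 28, 19, 0.026278, 41.05761, 149.40806)
  )
  colnames(rows) <- c("k", "n", "m", "p_printed", "or_printed", "cs_printed")
  as.data.frame(rows)
}

# Count pairs and reported one-sided p-values from the same study's results
# sections (up vs down and specific vs shared comparisons).
printed_count_pairs <- function() {
  data.frame(
    label = c("perturbed_up_down", "hub_up_down", "muscle_up_down",
              "adipose_up_down", "muscle_specific_shared"),
    a = c(38, 13, 247, 1426, 244),
    b = c(41, 9, 251, 1212, 217),
    p_printed = c(0.410983, 0.261216, 0.44653, 0.000017, 0.112959),
    stringsAsFactors = FALSE
  )
}
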