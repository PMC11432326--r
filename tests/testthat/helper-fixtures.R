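# Published characterization values used as generator truths and expected
# outputs across the suite.

# Thermal-inactivation table: per enzyme, block activation energy and the
# printed (T, kd, t1/2, dG*, dH*, dS*) rows (integer kelvins as typeset).
inactivation_reference <- function() {
  rbind(
    data.frame(enzyme = "WT", Ea = 49.42,
               temperature = c(353, 348, 343, 338),
               kd = c(0.0206, 0.0031, 0.0023, 0.0007),
               t_half = c(34, 224, 301, 990),
               dG = c(26.38, 27.30, 27.10, 27.50),
               dH = c(48.72, 48.73, 48.74, 48.75),
               dS = c(0.063, 0.062, 0.063, 0.063)),
    data.frame(enzyme = "Q274N", Ea = 35.64,
               temperature = c(353, 348, 343, 338),
               kd = c(0.0097, 0.0018, 0.0017, 0.0008),
               t_half = c(71, 385, 408, 866),
               dG = c(26.91, 27.68, 27.31, 27.41),
               dH = c(34.93, 34.94, 34.95, 34.96),
               dS = c(0.023, 0.021, 0.022, 0.022)),
    data.frame(enzyme = "R280K", Ea = 44.41,
               temperature = c(353, 348, 343, 338),
               kd = c(0.0335, 0.0037, 0.0013, 0.0009),
               t_half = c(21, 187, 533, 770),
               dG = c(26.04, 27.18, 27.49, 27.33),
               dH = c(43.71, 43.72, 43.73, 43.74),
               dS = c(0.050, 0.048, 0.047, 0.049)),
    data.frame(enzyme = "F325Y", Ea = 25.11,
               temperature = c(353, 348, 343, 338),
               kd = c(0.0079, 0.0062, 0.0038, 0.0016),
               t_half = c(88, 112, 182, 433),
               dG = c(27.05, 26.82, 26.76, 26.94),
               dH = c(24.42, 24.43, 24.44, 24.45),
               dS = c(-0.007, -0.007, -0.007, -0.007)))
}

# Kinetic-constants table: Km (mM), kcat (s^-1), Vmax (1e-7 mol min^-1),
# efficiency (mM^-1 s^-1) per enzyme and substrate.
kinetics_reference <- function() {
  tibble::tribble(
    ~enzyme,  ~substrate,      ~Km,   ~kcat,  ~Vmax_1e7, ~efficiency,
    "WT",     "his",           4.83,  12.239, 4.243,     2.5367,
    "WT",     "hisme",         8.77,  13.243, 4.591,     1.5101,
    "Q274N",  "his",          12.58,   1.925, 0.628,     0.1530,
    "Q274N",  "hisme",        47.21,   2.428, 0.793,     0.0514,
    "R280K",  "his",           7.99,   0.096, 0.231,     0.0120,
    "R280K",  "hisme",         3.43,   0.090, 0.021,     0.0262,
    "R280K",  "hisamide",      5.39,   0.220, 0.052,     0.0408,
    "F325Y",  "his",           3.38,   0.547, 0.273,     0.1617,
    "F325Y",  "hisme",        22.98,   0.454, 0.227,     0.0197,
    "F325Y",  "hisamide",      5.40,   0.008, 0.004,     0.0015)
}

# Apparent melting temperatures (K) and shifts vs wild type.
melt_reference <- function() {
  tibble::tribble(
    ~enzyme, ~Tm,     ~dTm,
    "WT",    357.36,  NA,
    "Q274N", 355.20, -2.16,
    "R280K", 358.80,  1.40,
    "F325Y", 351.85, -5.51)
}
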