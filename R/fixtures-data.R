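# Reference radius tables and summary statistics for the three-supplier
# Linezolid study (pilot + industrial scales).  Generated from the
# published tables; values are verbatim.  Do not edit by hand.

REFERENCE_SOURCES <- c("Glenmarck", "USV", "UQUIFA")

REFERENCE_RADII <- list(
  `Glenmarck.pilot` = matrix(c(
    4.29, 4.09, 4.16, 4.13, 4.18, 4.21, 4.24, 4.13, 4.16,  # Da
    5.48, 5.34, 5.38, 5.48, 5.42, 5.59, 5.58, 5.42, 5.44,  # Dc
    4.22, 4.77, 4.54, 4.97, 4.56, 4.89, 4.72, 4.80, 4.71,  # Ie
    4.34, 4.68, 4.54, 4.93, 4.58, 4.94, 4.80, 4.76, 4.71,  # IC
    1.59, 1.83, 2.13, 1.92, 1.76, 1.85, 1.54, 1.76, 1.62,  # Icd
    8.61, 8.47, 8.53, 8.37, 8.52, 8.36, 8.42, 8.44, 8.46,  # IH
    1.97, 1.27, 1.79, 1.17, 1.33, 1.30, 1.33, 1.55, 1.24,  # alpha
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # t
    9.83, 9.78, 9.76, 9.53, 9.78, 9.67, 9.65, 9.70, 9.65,  # HR
    10.00, 9.99, 9.99, 10.00, 10.00, 9.99, 10.00, 10.00, 9.99,  # H
    7.52, 7.45, 7.74, 7.72, 7.75, 7.57, 7.62, 7.90, 7.80,  # Pf
    4.50, 4.40, 3.65, 4.10, 3.60, 4.40, 4.60, 3.45, 3.90  # Itheta
  ), nrow = 12, byrow = TRUE, dimnames = list(
    c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta"),
    c("GL-1.R1", "GL-1.R2", "GL-1.R3", "GL-2.R1", "GL-2.R2", "GL-2.R3", "GL-3.R1", "GL-3.R2", "GL-3.R3"))),
  `USV.pilot` = matrix(c(
    2.59, 2.49, 2.63, 2.51, 2.48, 2.53, 2.47, 2.54, 2.58,  # Da
    3.56, 3.41, 3.56, 3.44, 3.34, 3.48, 3.38, 3.63, 3.56,  # Dc
    8.77, 9.03, 8.28, 8.98, 8.65, 8.99, 9.08, 9.85, 8.89,  # Ie
    5.45, 5.40, 5.22, 5.41, 5.15, 5.46, 5.38, 6.01, 5.51,  # IC
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # Icd
    8.13, 8.15, 8.23, 8.15, 8.27, 8.12, 8.16, 7.85, 8.10,  # IH
    0.51, 0.73, 0.84, 1.04, 0.74, 1.34, 0.90, 1.18, 0.74,  # alpha
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # t
    9.67, 9.65, 9.60, 9.62, 9.61, 9.57, 9.69, 9.52, 9.61,  # HR
    9.96, 9.98, 10.00, 10.00, 10.00, 10.00, 10.00, 10.00, 9.99,  # H
    9.18, 9.29, 9.34, 9.48, 9.59, 9.30, 9.44, 9.16, 9.38,  # Pf
    9.65, 9.40, 8.95, 9.25, 8.45, 8.20, 9.00, 8.75, 8.00  # Itheta
  ), nrow = 12, byrow = TRUE, dimnames = list(
    c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta"),
    c("US-1.R1", "US-1.R2", "US-1.R3", "US-2.R1", "US-2.R2", "US-2.R3", "US-3.R1", "US-3.R2", "US-3.R3"))),
  `UQUIFA.pilot` = matrix(c(
    2.36, 2.32, 2.40, 2.26, 2.29, 2.33, 2.28, 2.30, 2.34,  # Da
    2.72, 2.61, 2.68, 2.57, 2.63, 2.69, 2.62, 2.54, 2.68,  # Dc
    4.67, 3.99, 3.63, 4.45, 4.70, 4.79, 4.74, 3.42, 4.52,  # Ie
    2.65, 2.22, 2.09, 2.41, 2.59, 2.68, 2.60, 1.89, 2.54,  # IC
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # Icd
    9.24, 9.38, 9.42, 9.31, 9.26, 9.23, 9.25, 9.48, 9.27,  # IH
    1.27, 0.64, 1.55, 0.95, 0.65, 0.84, 0.49, 0.97, 0.47,  # alpha
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # t
    9.45, 9.83, 9.11, 8.86, 9.20, 9.91, 9.12, 9.78, 9.65,  # HR
    9.97, 9.97, 9.98, 9.97, 9.98, 9.99, 10.00, 9.97, 9.98,  # H
    2.96, 3.55, 3.76, 2.49, 3.15, 3.05, 3.13, 3.54, 2.78,  # Pf
    2.20, 2.15, 2.40, 2.70, 2.25, 2.40, 2.85, 2.50, 2.40  # Itheta
  ), nrow = 12, byrow = TRUE, dimnames = list(
    c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta"),
    c("UQ-1.R1", "UQ-1.R2", "UQ-1.R3", "UQ-2.R1", "UQ-2.R2", "UQ-2.R3", "UQ-3.R1", "UQ-3.R2", "UQ-3.R3"))),
  `Glenmarck.industrial` = matrix(c(
    4.14, 4.19, 4.23, 4.24, 4.16, 4.18, 4.20, 4.23, 4.25,  # Da
    5.42, 5.44, 5.41, 5.58, 5.44, 5.46, 5.56, 5.44, 5.57,  # Dc
    4.75, 4.57, 4.30, 4.72, 4.71, 4.67, 4.85, 4.38, 4.65,  # Ie
    4.72, 4.60, 4.36, 4.80, 4.71, 4.69, 4.89, 4.44, 4.74,  # IC
    2.08, 1.75, 2.13, 2.01, 2.03, 1.80, 2.11, 1.96, 1.76,  # Icd
    8.45, 8.51, 8.61, 8.42, 8.46, 8.47, 8.38, 8.57, 8.45,  # IH
    1.53, 1.22, 1.98, 1.45, 1.56, 1.01, 1.33, 2.19, 1.84,  # alpha
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # t
    9.58, 9.79, 9.78, 9.66, 9.77, 9.67, 9.65, 9.70, 9.75,  # HR
    9.99, 9.99, 10.00, 9.99, 10.00, 10.00, 9.99, 10.00, 9.99,  # H
    7.40, 7.75, 7.54, 7.53, 7.71, 7.55, 7.48, 7.86, 7.86,  # Pf
    4.50, 4.40, 4.15, 4.15, 3.95, 4.50, 4.10, 4.15, 3.65  # Itheta
  ), nrow = 12, byrow = TRUE, dimnames = list(
    c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta"),
    c("GL-4.R1", "GL-4.R2", "GL-4.R3", "GL-5.R1", "GL-5.R2", "GL-5.R3", "GL-6.R1", "GL-6.R2", "GL-6.R3"))),
  `USV.industrial` = matrix(c(
    2.58, 2.62, 2.55, 2.62, 2.49, 2.53, 2.55, 2.47, 2.58,  # Da
    3.56, 3.57, 3.65, 3.56, 3.41, 3.57, 3.59, 3.47, 3.62,  # Dc
    8.89, 8.46, 9.85, 10.00, 9.03, 9.60, 10.00, 9.72, 9.28,  # Ie
    5.51, 5.32, 6.03, 5.28, 5.40, 5.83, 5.79, 5.76, 5.75,  # IC
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # Icd
    8.10, 8.19, 7.84, 8.21, 8.15, 7.94, 7.96, 7.98, 7.98,  # IH
    0.72, 1.19, 0.96, 0.70, 1.38, 0.94, 0.76, 1.10, 0.96,  # alpha
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # t
    9.59, 9.68, 9.55, 9.69, 9.62, 9.61, 9.69, 9.64, 9.59,  # HR
    9.99, 9.99, 9.99, 9.96, 10.00, 9.99, 9.96, 9.99, 9.99,  # H
    9.40, 9.28, 9.39, 9.59, 9.38, 9.46, 9.48, 9.44, 9.46,  # Pf
    9.95, 8.40, 9.40, 9.60, 9.10, 8.90, 9.10, 9.80, 8.90  # Itheta
  ), nrow = 12, byrow = TRUE, dimnames = list(
    c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta"),
    c("US-4.R1", "US-4.R2", "US-4.R3", "US-5.R1", "US-5.R2", "US-5.R3", "US-6.R1", "US-6.R2", "US-6.R3"))),
  `UQUIFA.industrial` = matrix(c(
    2.28, 2.27, 2.32, 2.27, 2.29, 2.35, 2.26, 2.37, 2.35,  # Da
    2.58, 2.60, 2.68, 2.58, 2.69, 2.63, 2.57, 2.68, 2.67,  # Dc
    4.25, 4.66, 4.83, 4.41, 5.41, 3.78, 4.45, 4.07, 4.25,  # Ie
    2.33, 2.54, 2.69, 2.40, 2.97, 2.13, 2.41, 2.31, 2.40,  # IC
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # Icd
    9.34, 9.27, 9.22, 9.32, 9.13, 9.40, 9.31, 9.35, 9.32,  # IH
    0.95, 0.77, 1.35, 1.51, 0.65, 1.09, 1.05, 0.98, 1.35,  # alpha
    0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # t
    9.69, 9.83, 9.47, 9.26, 9.33, 9.92, 9.48, 9.77, 9.65,  # HR
    9.97, 9.98, 9.98, 9.97, 9.98, 9.99, 9.99, 9.99, 9.98,  # H
    3.17, 3.77, 3.53, 3.31, 3.35, 3.51, 3.06, 3.70, 3.57,  # Pf
    2.62, 2.15, 2.40, 2.17, 2.85, 2.50, 1.85, 2.40, 2.60  # Itheta
  ), nrow = 12, byrow = TRUE, dimnames = list(
    c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta"),
    c("UQ-4.R1", "UQ-4.R2", "UQ-4.R3", "UQ-5.R1", "UQ-5.R2", "UQ-5.R3", "UQ-6.R1", "UQ-6.R2", "UQ-6.R3")))
)

REFERENCE_STATS <- list(
  pilot = list(
    Glenmarck = matrix(c(
      4.1767, 0.0038, 0.0616, 1.4759,  # Da
      5.4589, 0.0071, 0.0840, 1.5393,  # Dc
      4.6871, 0.0498, 0.2232, 4.7630,  # Ie
      4.6966, 0.0365, 0.1912, 4.0702,  # IC
      1.7767, 0.0338, 0.1839, 10.3527,  # Icd
      8.4646, 0.0066, 0.0812, 0.9599,  # IH
      1.4387, 0.0758, 0.2753, 19.1339,  # alpha
      0.0000, 0.0000, 0.0000, 0.0000,  # t
      9.7052, 0.0087, 0.0933, 0.9610,  # HR
      9.9928, 0.0000, 0.0044, 0.0441,  # H
      7.6750, 0.0217, 0.1472, 1.9173,  # Pf
      4.0667, 0.1869, 0.4323, 10.6301,  # Itheta
      5.1782, 0.0011, 0.0338, 0.6527,  # PP
      4.9297, 0.0010, 0.0322, 0.6527  # IGC
    ), ncol = 4, byrow = TRUE, dimnames = list(
      c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta", "PP", "IGC"),
      c("mean", "variance", "sd", "cv_pct"))),
    USV = matrix(c(
      2.5356, 0.0030, 0.0548, 2.1612,  # Da
      3.4844, 0.0097, 0.0985, 2.8269,  # Dc
      8.9466, 0.1772, 0.4209, 4.7046,  # Ie
      5.4425, 0.0577, 0.2401, 4.4119,  # IC
      0.0000, 0.0000, 0.0000, 0.0000,  # Icd
      8.1290, 0.0134, 0.1159, 1.4255,  # IH
      0.8913, 0.0660, 0.2568, 28.8146,  # alpha
      0.0000, 0.0000, 0.0000, 0.0000,  # t
      9.6142, 0.0026, 0.0507, 0.5270,  # HR
      9.9904, 0.0002, 0.0152, 0.1524,  # H
      9.3496, 0.0192, 0.1384, 1.4802,  # Pf
      8.8500, 0.3063, 0.5534, 6.2531,  # Itheta
      5.6028, 0.0037, 0.0611, 1.0904,  # PP
      5.3339, 0.0034, 0.0582, 1.0904  # IGC
    ), ncol = 4, byrow = TRUE, dimnames = list(
      c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta", "PP", "IGC"),
      c("mean", "variance", "sd", "cv_pct"))),
    UQUIFA = matrix(c(
      2.3200, 0.0019, 0.0433, 1.8664,  # Da
      2.6378, 0.0035, 0.0595, 2.2570,  # Dc
      4.3239, 0.2645, 0.5143, 11.8939,  # Ie
      2.4062, 0.0771, 0.2777, 11.5428,  # IC
      0.0000, 0.0000, 0.0000, 0.0000,  # Icd
      9.3149, 0.0079, 0.0887, 0.9525,  # IH
      0.8706, 0.1319, 0.3632, 41.7191,  # alpha
      0.0000, 0.0000, 0.0000, 0.0000,  # t
      9.4340, 0.1429, 0.3780, 4.0072,  # HR
      9.9775, 0.0001, 0.0084, 0.0843,  # H
      3.1572, 0.1623, 0.4029, 12.7616,  # Pf
      2.4278, 0.0526, 0.2293, 9.4440,  # Itheta
      3.9058, 0.0023, 0.0483, 1.2372,  # PP
      3.7184, 0.0021, 0.0460, 1.2372  # IGC
    ), ncol = 4, byrow = TRUE, dimnames = list(
      c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta", "PP", "IGC"),
      c("mean", "variance", "sd", "cv_pct")))
  ),
  industrial = list(
    Glenmarck = matrix(c(
      4.2022, 0.0014, 0.0380, 0.9044,  # Da
      5.4798, 0.0048, 0.0692, 1.2637,  # Dc
      4.6226, 0.0326, 0.1805, 3.9054,  # Ie
      4.6615, 0.0284, 0.1686, 3.6175,  # IC
      1.9572, 0.0226, 0.1502, 7.6747,  # Icd
      8.4798, 0.0051, 0.0713, 0.8403,  # IH
      1.5681, 0.1422, 0.3771, 24.0471,  # alpha
      0.0000, 0.0000, 0.0000, 0.0000,  # t
      9.7051, 0.0054, 0.0737, 0.7591,  # HR
      9.9929, 0.0000, 0.0042, 0.0416,  # H
      7.6316, 0.0286, 0.1692, 2.2166,  # Pf
      4.1722, 0.0744, 0.2728, 6.5396,  # Itheta
      5.2061, 0.0004, 0.0211, 0.4044,  # PP
      4.9562, 0.0004, 0.0200, 0.4044  # IGC
    ), ncol = 4, byrow = TRUE, dimnames = list(
      c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta", "PP", "IGC"),
      c("mean", "variance", "sd", "cv_pct"))),
    USV = matrix(c(
      2.5544, 0.0027, 0.0522, 2.0446,  # Da
      3.5556, 0.0054, 0.0735, 2.0673,  # Dc
      9.4257, 0.2931, 0.5414, 5.7434,  # Ie
      5.6291, 0.0677, 0.2602, 4.6221,  # IC
      0.0000, 0.0000, 0.0000, 0.0000,  # Icd
      8.0395, 0.0159, 0.1260, 1.5667,  # IH
      0.9672, 0.0510, 0.2259, 23.3535,  # alpha
      0.0000, 0.0000, 0.0000, 0.0000,  # t
      9.6291, 0.0026, 0.0508, 0.5271,  # HR
      9.9823, 0.0003, 0.0161, 0.1617,  # H
      9.4299, 0.0073, 0.0852, 0.9033,  # Pf
      9.2389, 0.2436, 0.4936, 5.3423,  # Itheta
      5.7043, 0.0049, 0.0700, 1.2279,  # PP
      5.4305, 0.0044, 0.0667, 1.2279  # IGC
    ), ncol = 4, byrow = TRUE, dimnames = list(
      c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta", "PP", "IGC"),
      c("mean", "variance", "sd", "cv_pct"))),
    UQUIFA = matrix(c(
      2.2967, 0.0016, 0.0406, 1.7687,  # Da
      2.6244, 0.0029, 0.0536, 2.0440,  # Dc
      4.5299, 0.1599, 0.3998, 8.8265,  # Ie
      2.4959, 0.0452, 0.2125, 8.5151,  # IC
      0.0000, 0.0000, 0.0000, 0.0000,  # Icd
      9.2863, 0.0050, 0.0705, 0.7595,  # IH
      1.0722, 0.0809, 0.2844, 26.5214,  # alpha
      0.0000, 0.0000, 0.0000, 0.0000,  # t
      9.5498, 0.0388, 0.1970, 2.0625,  # HR
      9.9793, 0.0001, 0.0084, 0.0841,  # H
      3.3907, 0.0712, 0.2667, 7.8669,  # Pf
      2.3206, 0.1190, 0.3450, 14.8681,  # Itheta
      3.9621, 0.0045, 0.0672, 1.6971,  # PP
      3.7720, 0.0041, 0.0640, 1.6971  # IGC
    ), ncol = 4, byrow = TRUE, dimnames = list(
      c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta", "PP", "IGC"),
      c("mean", "variance", "sd", "cv_pct")))
  ),
  pooled = list(
    Glenmarck = matrix(c(
      4.1894, 0.0026, 0.0514, 1.2266,  # Da
      5.4693, 0.0057, 0.0755, 1.3798,  # Dc
      4.6549, 0.0399, 0.1997, 4.2907,  # Ie
      4.6790, 0.0309, 0.1758, 3.7571,  # IC
      1.8669, 0.0352, 0.1875, 10.0448,  # Icd
      8.4722, 0.0056, 0.0745, 0.8798,  # IH
      1.5034, 0.1070, 0.3271, 21.7591,  # alpha
      0.0000, 0.0000, 0.0000, 0.0000,  # t
      9.7052, 0.0066, 0.0815, 0.8401,  # HR
      9.9928, 0.0000, 0.0042, 0.0416,  # H
      7.6533, 0.0242, 0.1554, 2.0307,  # Pf
      4.1194, 0.1259, 0.3549, 8.6142,  # Itheta
      5.1922, 0.0010, 0.0308, 0.5941,  # PP
      4.9429, 0.0009, 0.0294, 0.5941  # IGC
    ), ncol = 4, byrow = TRUE, dimnames = list(
      c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta", "PP", "IGC"),
      c("mean", "variance", "sd", "cv_pct"))),
    USV = matrix(c(
      2.5450, 0.0028, 0.0528, 2.0759,  # Da
      3.5200, 0.0084, 0.0919, 2.6110,  # Dc
      9.1861, 0.2820, 0.5311, 5.7812,  # Ie
      5.5358, 0.0682, 0.2612, 4.7177,  # IC
      0.0000, 0.0000, 0.0000, 0.0000,  # Icd
      8.0842, 0.0159, 0.1261, 1.5600,  # IH
      0.9292, 0.0566, 0.2378, 25.5959,  # alpha
      0.0000, 0.0000, 0.0000, 0.0000,  # t
      9.6217, 0.0025, 0.0498, 0.5174,  # HR
      9.9864, 0.0002, 0.0158, 0.1580,  # H
      9.3898, 0.0141, 0.1189, 1.2662,  # Pf
      9.0444, 0.2988, 0.5466, 6.0437,  # Itheta
      5.6536, 0.0068, 0.0824, 1.4578,  # PP
      5.3822, 0.0062, 0.0785, 1.4578  # IGC
    ), ncol = 4, byrow = TRUE, dimnames = list(
      c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta", "PP", "IGC"),
      c("mean", "variance", "sd", "cv_pct"))),
    UQUIFA = matrix(c(
      2.3083, 0.0018, 0.0425, 1.8395,  # Da
      2.6311, 0.0031, 0.0554, 2.1056,  # Dc
      4.4269, 0.2109, 0.4593, 10.3744,  # Ie
      2.4511, 0.0597, 0.2443, 9.9675,  # IC
      0.0000, 0.0000, 0.0000, 0.0000,  # Icd
      9.3006, 0.0063, 0.0791, 0.8509,  # IH
      0.9714, 0.1109, 0.3330, 34.2803,  # alpha
      0.0000, 0.0000, 0.0000, 0.0000,  # t
      9.4919, 0.0891, 0.2984, 3.1440,  # HR
      9.9784, 0.0001, 0.0082, 0.0822,  # H
      3.2740, 0.1243, 0.3526, 10.7691,  # Pf
      2.3742, 0.0838, 0.2895, 12.1931,  # Itheta
      3.9340, 0.0041, 0.0638, 1.6209,  # PP
      3.7452, 0.0037, 0.0607, 1.6209  # IGC
    ), ncol = 4, byrow = TRUE, dimnames = list(
      c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t", "HR", "H", "Pf", "Itheta", "PP", "IGC"),
      c("mean", "variance", "sd", "cv_pct")))
  )
)

REFERENCE_PSD <- data.frame(
  source = c("Glenmarck", "USV", "UQUIFA"),
  D10 = c(13.053, 4.715, 2.813),
  D50 = c(59.635, 13.396, 8.865),
  D90 = c(163.493, 51.339, 30.443),
  Fprime = c(12.525, 10.888, 10.822))

REFERENCE_INCIDENCE <- matrix(c(
  4.18, 2.54, 2.32, 4.20, 2.55, 2.30, 4.19, 2.55, 2.31,  # Da
  5.46, 3.48, 2.64, 5.48, 3.56, 2.62, 5.47, 3.52, 2.63,  # Dc
  4.82, 3.01, 2.48, 4.84, 3.06, 2.46, 4.83, 3.03, 2.47,  # Dimensions
  4.69, 8.95, 4.32, 4.62, 9.43, 4.53, 4.65, 9.19, 4.43,  # Ie
  4.70, 5.44, 2.41, 4.66, 5.63, 2.50, 4.68, 5.54, 2.45,  # IC
  1.78, 0.00, 0.00, 1.96, 0.00, 0.00, 1.87, 0.00, 0.00,  # Icd
  3.72, 4.80, 2.24, 3.75, 5.02, 2.34, 3.73, 4.91, 2.29,  # Compressibility
  8.46, 8.13, 9.31, 8.48, 8.04, 9.29, 8.47, 8.08, 9.30,  # IH
  1.44, 0.89, 0.87, 1.57, 0.97, 1.07, 1.50, 0.93, 0.97,  # alpha
  0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,  # t
  3.30, 3.01, 3.40, 3.35, 3.00, 3.45, 3.33, 3.00, 3.42,  # Flowability
  9.71, 9.61, 9.43, 9.71, 9.63, 9.55, 9.71, 9.62, 9.49,  # HR
  9.99, 9.99, 9.98, 9.99, 9.98, 9.98, 9.99, 9.99, 9.98,  # H
  9.85, 9.80, 9.71, 9.85, 9.81, 9.76, 9.85, 9.80, 9.74,  # Lubricity/Stability
  7.68, 9.35, 3.16, 7.63, 9.43, 3.39, 7.65, 9.39, 3.27,  # Pf
  4.07, 8.85, 2.43, 4.17, 9.24, 2.32, 4.12, 9.04, 2.37,  # Itheta
  5.87, 9.10, 2.79, 5.90, 9.33, 2.86, 5.89, 9.22, 2.82,  # Lubricity/Dosage
  0.42, 0.58, 0.25, 0.42, 0.58, 0.25, 0.42, 0.58, 0.25,  # IP
  5.18, 5.60, 3.91, 5.21, 5.70, 3.96, 5.19, 5.65, 3.93,  # PP
  4.93, 5.33, 3.72, 4.96, 5.43, 3.77, 4.94, 5.38, 3.75  # IGC
), ncol = 9, byrow = TRUE, dimnames = list(
  c("Da", "Dc", "Dimensions", "Ie", "IC", "Icd", "Compressibility", "IH", "alpha", "t", "Flowability", "HR", "H", "Lubricity/Stability", "Pf", "Itheta", "Lubricity/Dosage", "IP", "PP", "IGC"),
  c("Glenmarck.pilot", "USV.pilot", "UQUIFA.pilot", "Glenmarck.industrial", "USV.industrial", "UQUIFA.industrial", "Glenmarck.average", "USV.average", "UQUIFA.average")))

REFERENCE_INDEX_ROWS <- list(
  `Glenmarck.pilot` = matrix(c(
    0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42,  # IP
    5.20, 5.17, 5.18, 5.18, 5.19, 5.12, 5.23, 5.18, 5.21, 5.16, 5.14, 5.17,  # PP
    4.95, 4.92, 4.94, 4.94, 4.94, 4.88, 4.98, 4.93, 4.96, 4.91, 4.89, 4.92  # IGC
  ), nrow = 3, byrow = TRUE, dimnames = list(
    c("IP", "PP", "IGC"),
    c("GL-1.R1", "GL-1.R2", "GL-1.R3", "GL-1.mean", "GL-2.R1", "GL-2.R2", "GL-2.R3", "GL-2.mean", "GL-3.R1", "GL-3.R2", "GL-3.R3", "GL-3.mean"))),
  `USV.pilot` = matrix(c(
    0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58,  # IP
    5.62, 5.63, 5.55, 5.60, 5.66, 5.52, 5.58, 5.59, 5.63, 5.71, 5.53, 5.62,  # PP
    5.35, 5.36, 5.29, 5.33, 5.38, 5.26, 5.32, 5.32, 5.36, 5.43, 5.26, 5.35  # IGC
  ), nrow = 3, byrow = TRUE, dimnames = list(
    c("IP", "PP", "IGC"),
    c("US-1.R1", "US-1.R2", "US-1.R3", "US-1.mean", "US-2.R1", "US-2.R2", "US-2.R3", "US-2.mean", "US-3.R1", "US-3.R2", "US-3.R3", "US-3.mean"))),
  `UQUIFA.pilot` = matrix(c(
    0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25,  # IP
    3.96, 3.89, 3.92, 3.92, 3.83, 3.89, 3.99, 3.90, 3.92, 3.87, 3.89, 3.89,  # PP
    3.77, 3.70, 3.73, 3.73, 3.65, 3.70, 3.80, 3.72, 3.73, 3.68, 3.70, 3.70  # IGC
  ), nrow = 3, byrow = TRUE, dimnames = list(
    c("IP", "PP", "IGC"),
    c("UQ-1.R1", "UQ-1.R2", "UQ-1.R3", "UQ-1.mean", "UQ-2.R1", "UQ-2.R2", "UQ-2.R3", "UQ-2.mean", "UQ-3.R1", "UQ-3.R2", "UQ-3.R3", "UQ-3.mean"))),
  `Glenmarck.industrial` = matrix(c(
    0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42, 0.42,  # IP
    5.21, 5.18, 5.21, 5.20, 5.21, 5.21, 5.17, 5.20, 5.21, 5.24, 5.21, 5.22,  # PP
    4.96, 4.94, 4.96, 4.95, 4.96, 4.96, 4.92, 4.95, 4.96, 4.99, 4.96, 4.97  # IGC
  ), nrow = 3, byrow = TRUE, dimnames = list(
    c("IP", "PP", "IGC"),
    c("GL-4.R1", "GL-4.R2", "GL-4.R3", "GL-4.mean", "GL-5.R1", "GL-5.R2", "GL-5.R3", "GL-5.mean", "GL-6.R1", "GL-6.R2", "GL-6.R3", "GL-6.mean"))),
  `USV.industrial` = matrix(c(
    0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58, 0.58,  # IP
    5.69, 5.56, 5.77, 5.67, 5.77, 5.66, 5.70, 5.71, 5.74, 5.78, 5.67, 5.73,  # PP
    5.42, 5.29, 5.49, 5.40, 5.49, 5.39, 5.42, 5.43, 5.47, 5.50, 5.40, 5.46  # IGC
  ), nrow = 3, byrow = TRUE, dimnames = list(
    c("IP", "PP", "IGC"),
    c("US-4.R1", "US-4.R2", "US-4.R3", "US-4.mean", "US-5.R1", "US-5.R2", "US-5.R3", "US-5.mean", "US-6.R1", "US-6.R2", "US-6.R3", "US-6.mean"))),
  `UQUIFA.industrial` = matrix(c(
    0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25,  # IP
    3.93, 3.99, 4.04, 3.99, 3.93, 4.05, 3.94, 3.98, 3.87, 3.97, 4.01, 3.95,  # PP
    3.74, 3.80, 3.84, 3.79, 3.74, 3.86, 3.75, 3.79, 3.68, 3.78, 3.82, 3.76  # IGC
  ), nrow = 3, byrow = TRUE, dimnames = list(
    c("IP", "PP", "IGC"),
    c("UQ-4.R1", "UQ-4.R2", "UQ-4.R3", "UQ-4.mean", "UQ-5.R1", "UQ-5.R2", "UQ-5.R3", "UQ-5.mean", "UQ-6.R1", "UQ-6.R2", "UQ-6.R3", "UQ-6.mean")))
)
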