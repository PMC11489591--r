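# Frozen reference values for the seawater carbonate system, computed with an
# independently coded solver (Newton iteration on free [H+], constants typed
# directly from the primary literature: Lueker et al. 2000 K1/K2, Dickson
# 1990a/b KB/KS, Dickson & Riley 1979 KF, Millero 1995 KW and pressure
# corrections, Uppstrom 1974 boron, Mucci 1983 calcite Ksp). Units: alk/dic
# umol/kg, temp deg C, pres dbar, co3 umol/kg, ph total scale.
reference_carbonate <- data.frame(
  alk = c(2300, 2300, 2300, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2200, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2400, 2300, 2300),
  dic = c(2100, 2000, 2100, 1900, 1900, 1900, 1900, 1900, 1900, 2050, 2050, 2050, 2050, 2050, 2050, 2250, 2250, 2250, 2250, 2250, 2250, 1900, 1900, 1900, 1900, 1900, 1900, 2050, 2050, 2050, 2050, 2050, 2050, 2250, 2250, 2250, 2250, 2250, 2250, 1900, 1900, 1900, 1900, 1900, 1900, 2050, 2050, 2050, 2050, 2050, 2050, 2250, 2250, 2250, 2250, 2250, 2250, 2150, 2150),
  sal = c(35, 35, 35, 30, 30, 30, 35, 35, 35, 30, 30, 30, 35, 35, 35, 30, 30, 30, 35, 35, 35, 30, 30, 30, 35, 35, 35, 30, 30, 30, 35, 35, 35, 30, 30, 30, 35, 35, 35, 30, 30, 30, 35, 35, 35, 30, 30, 30, 35, 35, 35, 30, 30, 30, 35, 35, 35, 34, 34),
  temp = c(10, 10, 2, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, -1, 10, 20, 4, 4),
  pres = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 100, 400),
  co3 = c(144.1359, 206.8857, 140.7847, 205.5859, 210.294, 214.3228, 198.0354, 203.1555, 207.6044, 110.497, 114.3877, 118.2012, 107.5826, 111.6861, 115.7269, 25.2901, 27.8859, 30.9994, 26.2786, 28.9651, 32.1799, 276.7929, 281.794, 285.79, 266.2044, 271.8009, 276.3963, 176.0348, 180.5658, 184.6387, 170.2491, 175.1176, 179.5371, 59.2274, 62.7447, 66.6381, 59.116, 62.7604, 66.7915, 350.9285, 355.8915, 359.5305, 337.279, 343.0402, 347.4815, 246.3515, 251.3332, 255.5238, 237.6542, 243.1317, 247.8204, 115.4734, 119.5459, 123.607, 112.805, 117.1042, 121.4061, 112.3267, 111.6957),
  ph = c(8.08434, 8.27777, 8.21241, 8.54464, 8.36293, 8.20563, 8.47408, 8.29375, 8.13774, 8.21827, 8.04159, 7.89033, 8.15381, 7.97844, 7.82845, 7.5322, 7.38277, 7.26324, 7.49706, 7.34751, 7.22777, 8.69194, 8.50827, 8.3488, 8.61975, 8.4375, 8.27937, 8.434, 8.2534, 8.09751, 8.36583, 8.18653, 8.03188, 7.89851, 7.73189, 7.59269, 7.84567, 7.68003, 7.54178, 8.815, 8.62967, 8.46842, 8.7415, 8.55765, 8.39779, 8.59587, 8.41301, 8.25459, 8.52577, 8.34424, 8.18708, 8.19598, 8.01931, 7.8683, 8.13309, 7.95769, 7.80793, 8.07002, 8.05842),
  omega = c(3.4334, 4.9282, 3.3679, 5.0465, 5.1547, 5.3119, 4.752, 4.8393, 4.9654, 2.7124, 2.8039, 2.9295, 2.5815, 2.6605, 2.7679, 0.6208, 0.6835, 0.7683, 0.6306, 0.69, 0.7697, 6.7944, 6.9073, 7.0831, 6.3877, 6.4745, 6.6107, 4.3211, 4.426, 4.5762, 4.0852, 4.1714, 4.2941, 1.4539, 1.538, 1.6516, 1.4185, 1.495, 1.5975, 8.6143, 8.7235, 8.9108, 8.0932, 8.1715, 8.3109, 6.0472, 6.1606, 6.333, 5.7026, 5.7916, 5.9272, 2.8345, 2.9303, 3.0635, 2.7068, 2.7895, 2.9037, 2.6432, 2.4744)
)
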