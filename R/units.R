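# Unit conventions.
#
# All user-facing quantities use the field's customary units:
#   velocity U       micrometre / second (um/s)
#   pressure dp      megapascal (MPa)
#   tube length L    metre (m)
#   viscosity eta    millipascal second (mPa*s), i.e. centipoise
#   conductivity k   square micrometre (um^2)
#
# Internally everything is converted to SI (m/s, Pa, m, Pa*s, m^2) in one
# place, here. The composite constant HP_UNIT_FACTOR is the single number by
# which U[um/s] = HP_UNIT_FACTOR * k[um^2] * dp[MPa] / (eta[mPa*s] * L[m]);
# it equals (1e-12 * 1e6 / 1e-3) * 1e6 = 1e3 and is exposed for the
# dimensional-soundness tests.

UM_PER_S_TO_M_PER_S <- 1e-6
MPA_TO_PA           <- 1e6
MPAS_TO_PAS         <- 1e-3
UM2_TO_M2           <- 1e-12
UM_TO_M             <- 1e-6
M_PER_S_TO_UM_PER_S <- 1e6

HP_UNIT_FACTOR <- UM2_TO_M2 * MPA_TO_PA / MPAS_TO_PAS * M_PER_S_TO_UM_PER_S
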