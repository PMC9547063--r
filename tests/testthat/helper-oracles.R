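# Frozen oracle values for the empirical rheology laws, computed with an
# independent numpy implementation of the published coefficient sets
# (viscosity and phase-separation logit law with A/B/X0 coefficients,
# Fahraeus tube/discharge relation inverted numerically).

ORACLE_MUREL <- data.frame(
    D  = c(10, 7, 100, 3.04, 5, 6, 12, 4, 8, 15, 25),
    Hd = c(0.0, 0.45, 0.45, 0.3, 0.3, 0.45, 0.3, 0.2, 0.6, 0.45, 0.1),
    mu = c(1.0, 1.2477174972058318, 2.4426340496931243,
           3.8465179523335102, 1.3138321247051294, 1.2735149967228097,
           1.1984989261716452, 1.5806756262983392, 1.4063072861280257,
           1.4704494064020857, 1.0946080496021582))

ORACLE_HD_FROM_HT <- data.frame(
    Ht = c(0.3, 0.2, 0.1, 0.25, 0.45, 0.4),
    D  = c(6, 4, 3.04, 5, 12, 8),
    Hd = c(0.40106469099157066, 0.2466240918204554, 0.10964800148752729,
           0.32814278757373927, 0.5755919268088471, 0.5217679439986681))

ORACLE_PHASE_SEP <- data.frame(
    fqb = c(0.5, 0.8, 0.2, 0.6, 0.3, 0.05, 0.98, 0.7),
    Df  = c(12, 12, 12, 15, 11, 12, 12, 20),
    Da  = c(6, 6, 6, 8, 5, 6, 6, 10),
    Db  = c(6, 6, 6, 6, 7, 6, 6, 10),
    Hd  = c(0.3, 0.3, 0.3, 0.45, 0.2, 0.3, 0.3, 0.4),
    fr  = c(0.5, 0.9099257541906575, 0.09007424580934273,
            0.6017426581224478, 0.23038555405127462, 0.0, 1.0,
            0.7495643385274252))

# independent forward Fahraeus relation (for inversion round trips)
oracle_ht_from_hd <- function(Hd, D) {
    X <- 1 + 1.7 * exp(-0.415 * D) - 0.6 * exp(-0.011 * D)
    Hd * (Hd + (1 - Hd) * X)
}

# closed-form Poiseuille conductance, um^3/(ms mmHg)
oracle_conductance <- function(D, L, mu = 1.2e-3, murel = 1) {
    0.133322 * pi * D^4 / (128 * L * mu * murel)
}
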