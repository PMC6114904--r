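# shared fixtures: parameter sets and a default environment

tbl1 <- function() cca_parameters()

env0 <- function() bond_environment()

# reduced-barrier variant of the reference landscape, cheap enough for the
# numerical oracles (grid MFPT, Brownian dynamics)
low_barrier_params <- function(E0 = 8, E1 = 2, H = 4, G = 1) {
  bond_parameters(E0 = E0, E1 = E1, H = H, G = G, d = 0.56, r0 = 1.7,
                  alpha_min = 48, alpha_c = 53, alpha_max = 169)
}

# barrier-less wide-angle limit (selectin-like); k1 > 0 unless E1 = 0
selectin_params <- function(E1 = 5.8) {
  bond_parameters(E0 = 21.8, E1 = E1, H = 0, G = 0, d = 0.56, r0 = 1.7,
                  alpha_min = 1, alpha_c = 90, alpha_max = 179)
}

# Bell slip-bond limit: angle-independent stiffness, no angular structure
bell_params <- function() selectin_params(E1 = 0)

# fast quadrature control for tests that loop over many parameter sets
ctl_fast <- function() numeric_control(n_theta = 400, n_r = 100,
                                       n_r_mfpt = 160, n_rup_nodes = 12)
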