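default_p <- transport_parameters()
default_d <- discretization()

surface_nmoll <- function(C_blood, u_sweat_n = 1, p = default_p,
                          d = default_d, method = "direct") {
  sweat_surface_nmol_l(simulate_steady_state(C_blood, u_sweat_n, p, d,
                                             method = method))
}
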