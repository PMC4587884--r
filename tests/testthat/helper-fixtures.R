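# shared objects for the suite; everything is generated in code
default_ls <- quartic_landscape()
default_cp <- critical_points(default_ls)

# independent root oracle: base-R polyroot on the expanded cubic
polyroot_oracle <- function(ls) {
  sort(Re(polyroot(c(ls$a * ls$q1, 2 * ls$a * ls$q2,
                     3 * ls$a * ls$q3, -4 * ls$a))))
}

quiet_params <- function(...) dynamics_params(...)
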