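.onLoad <- function(libname, pkgname) {
  # the flocking test model ships built in, at its full-scale defaults
  register_model(flocking_model())
  invisible()
}
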