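# shared fixtures: the standard model cell used in worked examples
# (fixed carbon density 150 gC/L, 10 um, non-motile, default parameters)
std_org <- function(...) organism(10, carbon = "C150", ...)

default_quota <- quota_params()        # N:C 0.05-0.18, KQ 10, G_max 0.693
default_env <- marine_environment()

# reference species trait rows by name
sp_row <- function(name) {
  sp <- species_reference()
  sp[sp$species == name, ]
}
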