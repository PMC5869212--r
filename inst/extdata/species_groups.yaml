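# Species vocabulary for the acoustic surveys: 11 species plus 3 merged
# acoustic groups whose calls cannot be reliably told apart, and the
# functional foraging guilds used in the group-level analyses.
species:
  - P. pipistrellus
  - P. pygmaeus
  - P. kuhlii/P. nathusii
  - B. barbastellus
  - M. alcathoe
  - M. brandtii/M. mystacinus
  - N. noctula
  - E. nilssonii
  - H. savii
  - Plecotus sp.
  - M. daubentonii
  - M. myotis
  - M. nattereri
  - V. murinus
acoustic_merges:
  P. kuhlii: P. kuhlii/P. nathusii
  P. nathusii: P. kuhlii/P. nathusii
  M. brandtii: M. brandtii/M. mystacinus
  M. mystacinus: M. brandtii/M. mystacinus
  P. auritus: Plecotus sp.
  P. austriacus: Plecotus sp.
functional_groups:
  edge_space:
    - P. pipistrellus
    - P. pygmaeus
    - P. kuhlii/P. nathusii
    - B. barbastellus
    - M. alcathoe
    - M. brandtii/M. mystacinus
  open_space:
    - N. noctula
    - E. nilssonii
    - H. savii
representative_species:
  open_space: N. noctula
  edge_space: P. pygmaeus
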