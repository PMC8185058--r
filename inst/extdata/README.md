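# Packaged fixtures

All files are UTF-8 TSV. Degree (°) and prime (′) characters in coordinate
strings are preserved verbatim.

## table1_soil.tsv / table2_water.tsv

Site-level physicochemical properties of peatland soil (15 sites) and water
(18 sites) across four regions of Northeast China: Sanjiang Plain (SJ),
Changbai Mountain (CB), Lesser Khingan Mountain (LK), Greater Khingan
Mountain (GK). Values are site means over three replicate plots; replicate-
level measurements are not available, so summaries are computed over sites.

Units (soil): pH unitless; TN, TP, DOC, TS, Fe2, Fe3, TFe in g/kg;
NH4, NO3, PO4, SO4, TMn in mg/kg; OM in %.
Units (water): pH unitless; all concentrations in mg/L except TMn
(10^-3 mg/kg as printed in the source table); ORP in mV (water only).

Notes:

- Coordinates are printed to arc-minute precision; decimal conversion is
  degrees + minutes/60 (no seconds term).
- The four JC soil rows carry a typographic coordinate form "126.22′E" in
  the source; they are normalized here to the degree-minute form 126°22′E,
  matching the identical JC sites in the water table.
- `region` is assigned from the printed coordinates (the four regions have
  distinct, well-separated locations). `peatland_type` (fen, fen_bog_complex,
  bog) is not recoverable from the published site tables and is left NA.

## guild_default.tsv

Genus -> guild reference for Fe(II)-oxidizing (FeOB) and Fe(III)-reducing
(FeRB) bacteria. This is a flat, user-extensible list assembled from genera
with well-documented iron redox metabolism (e.g. Gallionella, Leptothrix,
Sideroxydans among FeOB; Geobacter, Shewanella, Anaeromyxobacter, Geothrix
among FeRB), not a copy of any annotation database. It is intentionally a
superset of any one study's detections; extend or replace it via
`load_guild_reference(path)`.
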