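>base synthetic full-length sequence, Kunitz-like motifs planted
MKTLVAGPCKARNDESFYGGCGWQHIKLMNPRSTVYAEDCFGHIKLMNPQRSTVWYACDE
FGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWY
>del10 synthetic variant of base with an internal 10-residue deletion
MKTLVAGPCKARNDESFYGGCGWQHIKLMNPRSTVYAEDCFGHIKLMNPQRSTVWYACDE
FGHIKLMNPQRSTVWYACDETVWYACDEFGHIKLMNPQRSTVWY
>del25 synthetic variant of base truncated by 25 residues at the C-terminus
MKTLVAGPCKARNDESFYGGCGWQHIKLMNPRSTVYAEDCFGHIKLMNPQRSTVWYACDE
FGHIKLMNPQRSTVWYACDEFGHIKLMNPQRS
>unrelated synthetic sequence sharing no planted block with base
WWNNEEHHGGDDCCAAVVTTSSRRKKLLIIMMFFPPYYQQWWNNEEHHGGDDCCAAVVTT
SSRRKKLLIIMMFFPPYYQQWWNNEEHHGGDDCCAAVV
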