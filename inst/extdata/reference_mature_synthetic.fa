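>miR156 synthetic stand-in reference (family consensus, not a miRBase export)
UGACAGAAGAGAGUGAGCAC
>miR159 synthetic stand-in reference
UUUGGAUUGAAGGGAGCUCUA
>miR160 synthetic stand-in reference
UGCCUGGCUCCCUGUAUGCCA
>miR164 synthetic stand-in reference
UGGAGAAGCAGGGCACGUGCA
>miR166 synthetic stand-in reference
UCGGACCAGGCUUCAUUCCCC
>miR167 synthetic stand-in reference
UGAAGCUGCCAGCAUGAUCUA
>miR169 synthetic stand-in reference
UAGCCAAGGAUGACUUGCCUG
>miR171 synthetic stand-in reference
UGAUUGAGCCGCGCCAAUAUC
>miR172 synthetic stand-in reference
AGAAUCUUGAUGAUGCUGCAU
>miR319 synthetic stand-in reference
UUGGACUGAAGGGAGCUCCCU
>miR390 synthetic stand-in reference
AAGCUCAGGAGGGAUAGCGCC
>miR393 synthetic stand-in reference
UCCAAAGGGAUCGCAUUGAUC
>miR396 synthetic stand-in reference
UUCCACAGCUUUCUUGAACUG
>miR398 synthetic stand-in reference
UGUGUUCUCAGGUCACCCCUU
>miR408 synthetic stand-in reference
CUGCACUGCCUCUUCCCUGGC
>miR529 synthetic stand-in reference
AGAAGAGAGAGAGUACAGCUU
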