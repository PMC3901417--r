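family	identified_members	family_members	signal_gt_500
zma-miR156	zma-miR156a/j/k	zma-miR156a/b/c/d/e/f/g/h/i/l	no
	osa-miR156l	zma-miR156j	no
	ath-miR156g	zma-miR156k	no
zma-miR160	zma-miR160a	zma-miR160a/b/c/d/g/h	no
zma-miR162	zma-miR162	zma-miR162	no
	osa-miR162a/b		
zma-miR164	zma-miR164a/e/f/h	zma-miR164a/b/c/d/g	yes
	osa-miR164c/e	zma-miR164e	yes
	ath-miR164c	zma-miR164f	yes
		zma-miR164h	no
zma-miR167	zma-miR167a/e	zma-miR167a/b/c/d	yes
	ath-miR167c/d	zma-miR167e/f/g/h/i/j	yes
zma-miR168	zma-miR168a	zma-miR168a/b	yes
	osa-miR168a/b		
zma-miR171	zma-miR171b/c/d/g	zma-miR171b/d/e/i/j	no
		zma-miR171c	no
		zma-miR171g	no
zma-miR172	zma-miR172e	zma-miR172e	no
zma-miR319	zma-miR319a	zma-miR319a/b/c/d	yes
zma-miR390	zma-miR390a	zma-miR390a/b	no
zma-miR396	zma-miR396c	zma-miR396c/d	no
	osa-miR396f/g		
	sbi-miR396d		
zma-miR408	zma-miR408b*	zma-miR408b*	no
zma-miR528	zma-miR528a	zma-miR528a/b	yes
zma-miR529	zma-miR529	zma-miR529	no
	osa-miR529b		
zma-miR827	zma-miR827	zma-miR827	no
zma-miRs7	zma-miRs7	zma-miRs7	yes
zma-miRs9	zma-miRs9	zma-miRs9	no
zma-miRs16	zma-miRs16	zma-miRs16	no
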