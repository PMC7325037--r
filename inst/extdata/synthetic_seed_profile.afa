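>seed_ancestor
LGSWQNGEGCHHMVNDWIVCWEEYSHSMYCGPAKKKMHAKGYQMPQDQEWWQYQFRRENWSVDFNYLRLN
FLHNKMMDKSSFVIICWNFQIRTNILDGSGMWETLQVNPNFLEEKQHHKADVILFVAHLTECMQRVALKP
MEQLYRRYVPRVGYMPYHQFNQFNWMNYLQVSFHTFYIHLFYNWQYYYVAEDMMWLQQDMINYTWMSLSH
HKWTCTCVNEKARPMKEMNFFSPGIPPCDPHCHKKRINMHEMISVTHETWPDSACHNAVPVFIWAYKCIF
SQWWVPQAPFWSVFACFQIFYSTYTIKEGRSCIPTNRLLWTSNLGHCYCHFREGSAWLDN
>seedrow_001
LGSWDNGEGCHHMVNDWIVCWEEYSHSMYCGPAQKKMHAKGYQMPQDQEWWQYQFRRENWSVDFNYLRLN
FLHNKGMDKSSFVIICWNFQIATNILDGSGMWETLQVNPNFLEEKQHHKADVILFVAHLTECMQRVALKP
MEQLYRRYVPRSGYMPYNQFNQFNWMNYLQVSFHTFYIYLFYNWQYYYVANDMAWLQQDMINYTWMSWSH
HKWTCTCVNEKARPMIEMNFNSPGIPPCDPHCHKKRINMHEMISVTHETWPDCACHNRVPLFIWAYKCIF
CQWWVPQHPFWSVFACFQIFYSTYTIKEGLSCIPTNRLLWTSNLGHCYCNFREGSAWLDN
>seedrow_002
LGYWVNGEGCHHMVNDWITCSEEYMHGMYCGPAKKKMHAKGYQMPQDQIWWQYQFRRENWSVDFNYLRLN
FLHNKMMDKSSFVIICWNFQIRCNILDGEAMWETLQVNTNFLEEKGHPKADVILFVAHLTECMQRVALKP
MEQLYRRYVPRVGYMPYHQFNQFNWMNYLQVSFHTFYIHLFYNWQYYYVAEDMMWLQQDMINYTWMSLSH
HKWTCTCVNEKARPMKEMNFFSPGIPPCDPHCHKKRINMHEMISVTHETWPDSACINAVPVFIWAYKCIF
SQWWVPQATFWWIFACFQIFYQTYTIKEGRSCIPTNRLLETSNLGHFYHHFREGSAWLDN
>seedrow_003
LGSWQNGEGCHHMVNDWIVCWEEYSHSMYCGNADKKMIAKGYQMPQDQEWWQYQFRRENWSVDFNYLRLN
FLHNKMMPKSCFVIICWNFQIRTNILDGSGMWETLQVNPNFLEEKQHHKADVILFVAHLTECMQRVALKP
MEQLYRRYVPRVGYFPYMQFNQFNWMNYLQVSFHTFYIHLFYNWQYHYVAEDMMWLQQDMINYTWMSESH
HKWTCTCVNEFARPMKEMNFFSPGMPPCDPHCHDKRINMHGMISVTHETWPDSACHNAPPVFIWAYKCIF
SQWWVPQAPFWSVFACFQIFYSTTTIKEGRSCIPTNRLLWTSNLGHCYCMFREGSAWLDN
>seedrow_004
LGTWQNGEGCHHMVNDWIVCWEEYSVSMYCGPAKKKMHAKGYQMPQDQEWWQYQFRRENWTVDFNYLRDN
FDINKMMDKSSFVIICWNFQIRTNILDGSGMWETLQVNPNFLEEKQHHKADVILFAAHLTECMQRVALKP
MLQLYRRYVPRVGYMPYHQFNQFNWMNYLQVSFHTFYIHLFYNWQYYYVAFDMMWLQQDMINYTDMSLSH
HKWTCTCVNEKARPMHEMNFFSPQIPPCDPHAHKKRINMHEMISGTHETWPDSACHNAVPVFIWAYKCIF
SQWWVPQAPFWSHFACFQIFYSTYTIKEGRSCIPTNRLLWTSNLGHCYCHFREVSAWLDN
>seedrow_005
LGSWQNGKGCHHMVNDWIVCWEEYSHSMYCGPAKKKMHAKGYQEPQDQEWWQYQFPRENWSVDFNYLRLN
FLHNKMMDKSSFVIICWNFQIRTNILDGSGMWEELQVNPNFLEEAQHHKADVILFVAHLTECMQRVALKP
MEQLYRRYVPRVGYMPYHSFNQFNWMNYLQVSFHTFDIHLTYNWQYYYVAEDMMWLQQHMINYTWMSLCH
IKWTCTCVNEKFRPMKEMNFFSPGIPPCDPHCHKKRINMHEMISVTHWMWPESACHNAVPVFIWAYKCIF
SQWWVPQAPFWSVFACFQIFYSTYTIKEGRSCIPTNRLLWTSNLGQCYCHFREGSAWLDN
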