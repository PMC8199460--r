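HOLA	1000
GRACIAS	990
BUENOS	980
DIAS	970
CASA	960
TIEMPO	950
MANANA	940
EXAMEN	620
EXITO	615
EXTRA	610
EXCESO	605
EXTERNO	600
EXACTO	595
EXISTE	590
USO	580
USUARIO	575
UTIL	570
URGENTE	565
UVA	560
USTED	555
URBANO	550
ROJO	540
ROSA	535
RATON	530
RAPIDO	525
ROPA	520
RUEDA	515
RELOJ	510
FRANCISCO	300
EXPERIMENTO	290
UNIVERSIDAD	280
RICARDO	270
PAULA	260
FELIZ	250
NAVIDAD	240
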