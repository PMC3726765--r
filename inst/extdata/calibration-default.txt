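# coassoc calibration model: f(z) = exp(a + b*|z| + c*z^2)
a: 0
b: -0.23898413125892792
c: 0.73212908322210568
r_squared: 0.82878753494283075
sigma: 0.26236805945376018
z_min: 4.508405431337323e-06
z_max: 1.8335961549034914
n_cal: 10000
reps_cal: 500
seed: 101
version: 0.2.0
[grid]
maf1	maf2	r_target	z_bar	rel_var	n_cal	reps_cal
0.1	0.1	0	1.9091580688228782e-4	0.853587975598915	10000	500
0.1	0.1	0.15	0.15058296016453546	1.3412982068794834	10000	500
0.1	0.1	0.3	0.30949761144775173	1.7065076365718952	10000	500
0.1	0.1	0.45	0.4852877519407914	2.0528792045416506	10000	500
0.1	0.1	0.6	0.6923202108444604	2.5831705010094357	10000	500
0.1	0.1	0.75	0.972466671110958	3.312725098810183	10000	500
0.1	0.1	0.9	1.4718120688054714	8.246208664433862	10000	500
0.1	0.1	0.95	1.832839521726354	14.613712264433062	10000	500
0.1	0.2	0	-1.5112208058942045e-4	1.1522528841685278	10000	500
0.1	0.2	0.15	0.15081878897400688	1.1580568074691748	10000	500
0.1	0.2	0.3	0.30963227657209946	1.4087878800129756	10000	500
0.1	0.2	0.45	0.4848363280693958	1.4386548472180634	10000	500
0.1	0.2	0.6	0.6934808185578314	1.5031142034682288	10000	500
0.2	0.2	0	-8.596939647388215e-4	1.12587230346126	10000	500
0.2	0.2	0.15	0.15085235084686852	1.152599112323673	10000	500
0.2	0.2	0.3	0.3107878172819392	1.2048976620570127	10000	500
0.2	0.2	0.45	0.48554348085585775	1.2268071865649068	10000	500
0.2	0.2	0.6	0.6934594284469562	1.4993835072419524	10000	500
0.2	0.2	0.75	0.9723678428602451	1.9568471102083709	10000	500
0.2	0.2	0.9	1.4723293402525757	4.733200798199763	10000	500
0.2	0.2	0.95	1.8330742715851691	8.072943067000903	10000	500
0.1	0.30000000000000004	0	-3.2884249093840704e-4	0.9937463814162583	10000	500
0.1	0.30000000000000004	0.15	0.15100360581425612	1.2019846536392722	10000	500
0.1	0.30000000000000004	0.3	0.30927154201049323	1.1074136734108113	10000	500
0.1	0.30000000000000004	0.45	0.4850242828025852	1.2836063967781037	10000	500
0.1	0.30000000000000004	0.6	0.6930278162857623	1.1279601439236793	10000	500
0.2	0.30000000000000004	0	0.0011048007611426023	0.9568817763022226	10000	500
0.2	0.30000000000000004	0.15	0.15113921603734895	1.1010501417323058	10000	500
0.2	0.30000000000000004	0.3	0.3092574027386343	1.0410779282255362	10000	500
0.2	0.30000000000000004	0.45	0.48417005320484685	1.2372911274009295	10000	500
0.2	0.30000000000000004	0.6	0.6932881532969494	1.2687839978356408	10000	500
0.2	0.30000000000000004	0.75	0.9731269379020845	1.075834147009953	10000	500
0.30000000000000004	0.30000000000000004	0	-2.905158290456299e-4	1.1000201180771578	10000	500
0.30000000000000004	0.30000000000000004	0.15	0.1511673046823506	1.080911856444936	10000	500
0.30000000000000004	0.30000000000000004	0.3	0.30906833921258503	1.1496975695618408	10000	500
0.30000000000000004	0.30000000000000004	0.45	0.48423016831204224	1.068012283138035	10000	500
0.30000000000000004	0.30000000000000004	0.6	0.6925801099061203	1.0397907923343899	10000	500
0.30000000000000004	0.30000000000000004	0.75	0.9730639981401544	1.528980049767703	10000	500
0.30000000000000004	0.30000000000000004	0.9	1.472370951519787	3.132522257807982	10000	500
0.30000000000000004	0.30000000000000004	0.95	1.8335961549034914	6.707147751944023	10000	500
0.1	0.4	0	-4.508405431337323e-6	0.9603205457037747	10000	500
0.1	0.4	0.15	0.1508179930238485	1.047090973249878	10000	500
0.1	0.4	0.3	0.3093936796779311	1.0218764221024714	10000	500
0.1	0.4	0.45	0.48448690177619014	0.9548606374725314	10000	500
0.1	0.4	0.6	0.6927281872122225	0.8915057286373284	10000	500
0.2	0.4	0	0.0012588150224705828	1.0979949267256377	10000	500
0.2	0.4	0.15	0.15113551715155965	0.9366377123689412	10000	500
0.2	0.4	0.3	0.3095970224072132	0.973519976970326	10000	500
0.2	0.4	0.45	0.48518891558179134	1.0017851499693964	10000	500
0.2	0.4	0.6	0.69249820899101	0.9531210002073731	10000	500
0.30000000000000004	0.4	0	5.96552626954222e-4	0.9973596709358411	10000	500
0.30000000000000004	0.4	0.15	0.15094380340630145	1.0997027641706862	10000	500
0.30000000000000004	0.4	0.3	0.30966603749144084	1.0665414589361195	10000	500
0.30000000000000004	0.4	0.45	0.48495406926344026	1.047792478842019	10000	500
0.30000000000000004	0.4	0.6	0.6933503733273967	0.9200110969958769	10000	500
0.30000000000000004	0.4	0.75	0.9730997323134957	1.1260695009518558	10000	500
0.4	0.4	0	-3.271702664206856e-4	0.9770465005624508	10000	500
0.4	0.4	0.15	0.1508097840109648	0.9457777443355224	10000	500
0.4	0.4	0.3	0.30956040292985737	1.1884286823438552	10000	500
0.4	0.4	0.45	0.4845681293322896	1.1150345690588266	10000	500
0.4	0.4	0.6	0.6930101198700591	1.092769680749065	10000	500
0.4	0.4	0.75	0.9725669425817264	1.3124774856465535	10000	500
0.4	0.4	0.9	1.472732332170975	2.5885307415003886	10000	500
0.4	0.4	0.95	1.8308782765260456	5.501607883123646	10000	500
0.1	0.5	0	-3.7911376381246763e-4	1.104865564490837	10000	500
0.1	0.5	0.15	0.1511354479359756	1.0098384450327222	10000	500
0.1	0.5	0.3	0.30913212217953734	0.764273873580613	10000	500
0.1	0.5	0.45	0.48436216833478857	0.82062828157292	10000	500
0.1	0.5	0.6	0.6931232332825391	0.7413070990405625	10000	500
0.2	0.5	0	3.942178908349658e-4	0.9993409271949532	10000	500
0.2	0.5	0.15	0.15120286019465984	1.0128522397919328	10000	500
0.2	0.5	0.3	0.30996471944815585	0.9964418786740574	10000	500
0.2	0.5	0.45	0.4849163567279629	0.9035463647213026	10000	500
0.2	0.5	0.6	0.6935336330578891	0.700975016029595	10000	500
0.30000000000000004	0.5	0	-1.1784969062115797e-4	0.9027377812527326	10000	500
0.30000000000000004	0.5	0.15	0.1508952745710571	0.983073070362717	10000	500
0.30000000000000004	0.5	0.3	0.30958968644594037	1.1400424509643663	10000	500
0.30000000000000004	0.5	0.45	0.48458968843333944	0.9254181044693701	10000	500
0.30000000000000004	0.5	0.6	0.693009870878128	0.8400163766804081	10000	500
0.4	0.5	0	4.262732165450021e-4	0.9623841568218531	10000	500
0.4	0.5	0.15	0.1513930357359255	0.9223181880772131	10000	500
0.4	0.5	0.3	0.30997328271232355	0.9959995155172191	10000	500
0.4	0.5	0.45	0.4842004055746637	1.0494258072112415	10000	500
0.4	0.5	0.6	0.6927781600064851	1.0341582722086782	10000	500
0.4	0.5	0.75	0.9734786371373654	0.9052872006093167	10000	500
0.5	0.5	0	3.383720580709919e-4	0.9351986170083952	10000	500
0.5	0.5	0.15	0.15152370898515125	0.985028094846965	10000	500
0.5	0.5	0.3	0.31031110805704826	0.9682304059975889	10000	500
0.5	0.5	0.45	0.4851932049669735	1.0956231913107288	10000	500
0.5	0.5	0.6	0.6936727215376592	1.0851156966895756	10000	500
0.5	0.5	0.75	0.9737368106322125	1.3238269432624366	10000	500
0.5	0.5	0.9	1.4728860368933008	2.5570623541777984	10000	500
0.5	0.5	0.95	1.8329649856375712	5.520444944668299	10000	500
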